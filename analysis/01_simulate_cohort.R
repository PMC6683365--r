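#!/usr/bin/env Rscript
# Simulate the study cohort: 7 surfactant-treated and 5 control preterm
# lambs, each with a physiological time course (0-120 min) and a lung
# section whose peptide abundance is driven by the same latent
# peripheral-deposition factor.  Writes the sections as imzML/ibd pairs,
# the physiology as TSV and the ground truth as JSON sidecars.

suppressMessages(library(surfmsi))

seed <- 1L
out_msi <- "results/msi"
dir.create(out_msi, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(cohort_sim_params(seed = seed))
write_physio_tsv(cohort$physio, "results/physiology.tsv")

for (id in names(cohort$section_params)) {
  sec <- generate_section(cohort$section_params[[id]])
  write_imzml(sec, file.path(out_msi, paste0(id, ".imzML")))
  write_truth_json(sec, file.path(out_msi, paste0(id, "_truth.json")))
}
readr::write_tsv(cohort$truth, "results/cohort_truth.tsv")

message(sprintf(
  "simulated %d treated + %d control animals (seed %d); deposition range %.2f-%.2f",
  sum(cohort$truth$group == "treated"), sum(cohort$truth$group == "control"),
  seed,
  min(cohort$truth$deposition[cohort$truth$group == "treated"]),
  max(cohort$truth$deposition[cohort$truth$group == "treated"])))
message("sections written to ", out_msi, "; physiology to results/physiology.tsv")
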