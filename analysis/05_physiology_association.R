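#!/usr/bin/env Rscript
# Physiology processing and association with the MSI summaries:
# log10 transform of the blood gases, per-animal AUC and 120-min endpoint,
# treated-vs-control t-tests routed through Levene's test, and Spearman
# correlation of PaO2/Cdyn/PIP AUC with Avg_log10_I and Sum_log10_I of
# both peptide channels over the treated animals.

suppressMessages(library(surfmsi))

physio <- read_physio_tsv("results/physiology.tsv")
summaries <- summarize_physio(transform_physio(physio))
readr::write_tsv(summaries, "results/physio_summaries.tsv")

tests <- group_compare_all(summaries)
readr::write_tsv(tests, "results/group_tests.tsv")
message("group comparisons (AUC), ordered by p-value:")
print(dplyr::arrange(tests[tests$summary == "auc", ], .data$p_value))

msi <- readr::read_tsv("results/section_summaries.tsv", show_col_types = FALSE)
assoc <- associate(summaries, msi)
readr::write_tsv(assoc, "results/associations.tsv")
message("Spearman associations over treated animals:")
print(dplyr::arrange(assoc, .data$ion, .data$parameter))

spb <- assoc[assoc$ion == "SP-B analog" & assoc$metric == "sum_log10_I", ]
message(sprintf(
  "SP-B analog Sum_log10_I: rho = %+.2f (PaO2_AUC), %+.2f (Cdyn_AUC), %+.2f (PIP_AUC)",
  spb$rho[spb$parameter == "PaO2_AUC"],
  spb$rho[spb$parameter == "Cdyn_AUC"],
  spb$rho[spb$parameter == "PIP_AUC"]))
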