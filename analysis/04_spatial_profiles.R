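#!/usr/bin/env Rscript
# Distance-from-border profiles of the SP-C analog signal for each
# treated section: pixels binned by Euclidean distance to the tissue
# border (15 equal-width bins over 0.7-35.5 pixels), median corrected
# signal per bin.

suppressMessages(library(surfmsi))

truth <- readr::read_tsv("results/cohort_truth.tsv", show_col_types = FALSE)
treated <- truth$animal_id[truth$group == "treated"]
controls <- truth$animal_id[truth$group == "control"]

datasets <- Map(read_imzml,
                file.path("results/msi", paste0(truth$animal_id, ".imzML")),
                group = truth$group)
pr <- process_sections(datasets, ions = c("SP-C analog" = 3618))

profiles <- list()
for (id in treated) {
  s <- pr$samples[[id]]
  dist <- distance_to_border(s$tissue)
  prof <- bin_by_distance(dist, s$ions[["SP-C analog"]]$corrected)
  prof$animal_id <- id
  profiles[[id]] <- prof
}
profiles <- dplyr::bind_rows(profiles)
readr::write_tsv(profiles, "results/distance_profiles.tsv")

# direction of the border-distance trend per animal (positive Spearman
# means the signal rises away from the border, i.e. toward the centre)
trend <- profiles |>
  dplyr::filter(!is.na(.data$median_signal)) |>
  dplyr::group_by(.data$animal_id) |>
  dplyr::summarise(rho = suppressWarnings(
    stats::cor(.data$dist_mid, .data$median_signal, method = "spearman")))
print(trend)
message(sprintf("%d of %d treated sections show signal rising away from the border",
                sum(trend$rho > 0), nrow(trend)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  for (id in treated[1]) {
    p <- plot_distance_profile(profiles[profiles$animal_id == id, ], id)
    ggplot2::ggsave(file.path("results/figures",
                              sprintf("profile_%s.png", id)),
                    p, width = 5, height = 4, dpi = 120)
  }
}
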