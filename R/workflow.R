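# End-to-end section processing: ties msi_io, preprocess and spatial_stats
# together across a cohort of lung sections.  Each ion channel is processed
# independently (its own background model per sample); the noise threshold
# is estimated once per ion from the pooled corrected tissue pixels of the
# control sections and applied to every sample.

#' Process a cohort of lung sections for a set of ions
#'
#' Per sample and ion: extract the ion image, log-transform, segment
#' tissue, estimate the background model and subtract its density mode.
#' Per ion: pool corrected tissue pixels of the control samples and take
#' the configured quantile as the noise threshold, then flag above-noise
#' pixels and compute section summaries.
#'
#' @param datasets list of [msi_dataset()] sections (mixed treated and
#'   control; group is read from each dataset).
#' @param ions named numeric vector of target m/z values, names are ion
#'   labels.  Default: the SP-C analog sodium adduct and the protonated
#'   SP-B analog.
#' @param tolerance extraction half-width in Da.
#' @param quantile noise-threshold quantile on pooled control pixels.
#' @param pseudocount for the log transform.
#' @param mode_on passed to [background_model()].
#' @return A list with `summaries` (tibble over samples x ions),
#'   `thresholds` (named per ion), and `samples` (per sample: tissue mask
#'   and, per ion, the corrected image, background model, masks).
#' @export
process_sections <- function(datasets,
                             ions = c("SP-C analog" = 3618,
                                      "SP-B analog" = 3886),
                             tolerance = 1, quantile = 0.995,
                             pseudocount = 1, mode_on = "all") {
  stopifnot(length(datasets) > 0L)
  groups <- vapply(datasets, function(d) d$group, character(1))
  if (!any(groups == "control")) {
    stop("need at least one control section to estimate the noise threshold")
  }
  samples <- lapply(datasets, function(d) {
    tissue <- segment_tissue(d)
    per_ion <- lapply(seq_along(ions), function(j) {
      pre <- preprocess_ion(d, ions[[j]], tolerance = tolerance,
                            pseudocount = pseudocount, tissue = tissue,
                            mode_on = mode_on)
      pre[c("corrected", "model")]
    })
    names(per_ion) <- names(ions)
    list(sample_id = d$sample_id, group = d$group,
         tissue = tissue, ions = per_ion)
  })
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")

  thresholds <- vapply(names(ions), function(lab) {
    pool <- unlist(lapply(samples[groups == "control"], function(s) {
      v <- s$ions[[lab]]$corrected$values
      v[s$tissue & !is.na(v)]
    }))
    estimate_noise_threshold(pool, quantile)
  }, numeric(1))

  rows <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (lab in names(ions)) {
      corr <- s$ions[[lab]]$corrected
      an <- above_noise_mask(corr, thresholds[[lab]], s$tissue)
      masks <- pixel_masks(tissue = s$tissue, above_noise = an,
                           background = s$tissue & !an)
      samples[[i]]$ions[[lab]]$masks <- masks
      sm <- section_summary(corr, masks, ion = lab)
      sm$group <- s$group
      rows[[length(rows) + 1L]] <- sm
    }
  }
  list(summaries = dplyr::bind_rows(rows),
       thresholds = thresholds,
       samples = samples)
}

#' Write a matrix as a TSV grid
#'
#' @param m numeric or logical matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_grid_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}
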