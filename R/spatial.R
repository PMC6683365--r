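# Section-level summaries and distance-from-border profiles.
#
# Avg_log10_I: mean corrected log10 intensity over all tissue pixels.
# Sum_log10_I: sum of corrected log10 intensities over above-noise pixels
# (computed on the log scale, consistent with all statistics being run on
# log-transformed data; the raw-scale alternative is available via
# `sum_on = "raw"`).

#' Section-level intensity summary for one ion
#'
#' @param corrected corrected [log_ion_image()].
#' @param masks a [pixel_masks()] consistent with the image grid.
#' @param ion ion label (e.g. `"SP-C analog"`).
#' @param sum_on `"log"` (default: sum of log10-corrected intensities over
#'   above-noise pixels) or `"raw"` (log10 of the summed back-transformed
#'   intensities).
#' @return A tibble with `sample_id`, `ion`, `avg_log10_I`, `sum_log10_I`,
#'   `n_tissue`, `n_above_noise`.
#' @export
section_summary <- function(corrected, masks, ion = "SP-C analog",
                            sum_on = c("log", "raw")) {
  sum_on <- match.arg(sum_on)
  stopifnot(inherits(corrected, "log_ion_image"),
            inherits(masks, "pixel_masks"))
  v <- corrected$values
  if (!identical(dim(v), dim(masks$tissue))) {
    stop("mask grid does not match the image grid")
  }
  tis <- masks$tissue & !is.na(v)
  if (!any(tis)) stop("empty tissue mask")
  an <- masks$above_noise & !is.na(v)
  s <- if (!any(an)) 0 else if (sum_on == "log") {
    sum(v[an])
  } else {
    log10(sum(10^v[an]))
  }
  tibble::tibble(
    sample_id = corrected$sample_id,
    ion = ion,
    avg_log10_I = mean(v[tis]),
    sum_log10_I = s,
    n_tissue = sum(tis),
    n_above_noise = sum(an))
}

#' Euclidean distance from the tissue border
#'
#' For every tissue pixel, the Euclidean distance (in pixel units) to the
#' nearest off-tissue pixel; the grid edge counts as border, so a tissue
#' mask touching the edge still has finite distances.  Off-tissue pixels
#' are `NA`.  Backed by an exact Euclidean distance transform on a
#' background-padded grid.
#'
#' @param tissue logical rows x cols matrix.
#' @return Numeric matrix of distances (`NA` off tissue).
#' @export
distance_to_border <- function(tissue) {
  stopifnot(is.logical(tissue), is.matrix(tissue))
  if (!any(tissue)) stop("empty tissue mask")
  pad <- matrix(0, nrow(tissue) + 2L, ncol(tissue) + 2L)
  pad[2:(nrow(tissue) + 1L), 2:(ncol(tissue) + 1L)] <- tissue * 1
  dm <- EBImage::distmap(EBImage::Image(t(pad)), metric = "euclidean")
  d <- t(EBImage::imageData(dm))[2:(nrow(tissue) + 1L),
                                 2:(ncol(tissue) + 1L), drop = FALSE]
  d[!tissue] <- NA_real_
  d
}

#' Bin corrected intensities by distance from the tissue border
#'
#' Equal-width, non-overlapping bins over the distance range (default
#' 0.7-35.5 pixels); each bin's signal is the median corrected intensity of
#' its pixels.  Pixels outside the range are excluded.
#'
#' @param distance distance matrix from [distance_to_border()].
#' @param corrected corrected [log_ion_image()].
#' @param n_bins number of bins (>= 2), default 15.
#' @param range distance range in pixels, default `c(0.7, 35.5)`.
#' @return A tibble with `bin`, `dist_lo`, `dist_hi`, `dist_mid`,
#'   `median_signal`, `n_pixels` (median `NA` for empty bins).
#' @export
bin_by_distance <- function(distance, corrected, n_bins = 15L,
                            range = c(0.7, 35.5)) {
  stopifnot(inherits(corrected, "log_ion_image"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (range[2L] <= range[1L]) stop("distance range must be increasing")
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  v <- corrected$values
  ok <- !is.na(distance) & !is.na(v) &
    distance >= range[1L] & distance <= range[2L]
  if (!any(ok)) stop("no pixels fall inside the distance range: all bins empty")
  # right-closed bins; the first bin includes its left edge
  idx <- findInterval(distance[ok], edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[distance[ok] == edges[1L]] <- 1L
  med <- rep(NA_real_, n_bins)
  cnt <- integer(n_bins)
  agg <- tapply(v[ok], factor(idx, levels = seq_len(n_bins)),
                stats::median)
  tab <- table(factor(idx, levels = seq_len(n_bins)))
  med[] <- as.numeric(agg)
  cnt[] <- as.integer(tab)
  tibble::tibble(
    bin = seq_len(n_bins),
    dist_lo = edges[-(n_bins + 1L)],
    dist_hi = edges[-1L],
    dist_mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
    median_signal = med,
    n_pixels = cnt)
}
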