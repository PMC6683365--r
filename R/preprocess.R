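# Normalization chain for ion images: log10 transform, tissue segmentation
# from the total ion current, background identification by two-population
# clustering of log intensities, batch correction by subtracting the mode
# of the log-intensity density (which sets the mean background intensity to
# zero), and a noise threshold taken as the 99.5% quantile of pooled,
# corrected control-section intensities.

#' Log10-transform an ion image
#'
#' @param image an [ion_image()].
#' @param pseudocount positive constant added before the log; default 1 raw
#'   unit (TOF counts are non-negative and O(10-10^4)).
#' @return A [log_ion_image()]; missing pixels stay missing.
#' @export
log_transform <- function(image, pseudocount = 1) {
  stopifnot(inherits(image, "ion_image"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log_ion_image(log10(image$values + pseudocount), pseudocount,
                target_mz = image$target_mz, tolerance = image$tolerance,
                sample_id = image$sample_id, group = image$group)
}

#' Total ion current image
#'
#' Per-pixel sum of all peak intensities; the substrate for tissue
#' segmentation.
#'
#' @param dataset an [msi_dataset()].
#' @return An [ion_image()] with `target_mz = NA`.
#' @export
total_ion_current <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  vals <- matrix(NA_real_, dataset$grid_shape[1L], dataset$grid_shape[2L])
  vals[cbind(dataset$coords$y + 1L, dataset$coords$x + 1L)] <-
    vapply(dataset$intensity, sum, numeric(1))
  structure(
    list(values = vals, target_mz = NA_real_, tolerance = NA_real_,
         sample_id = dataset$sample_id, group = dataset$group),
    class = "ion_image")
}

#' Segment the tissue region of a slide
#'
#' Thresholds the log10 total ion current at its between-class (Otsu)
#' optimum, applies a morphological closing, and keeps the largest
#' connected component.  A calibration slide coated with homogenate is
#' expected to segment as (nearly) the full grid.
#'
#' @param dataset an [msi_dataset()].
#' @param closing_radius radius of the closing brush in pixels.
#' @param min_tissue_fraction if the thresholded foreground covers less
#'   than this fraction of the acquired pixels, the slide is taken to be
#'   uniformly coated (e.g. a homogenate-covered calibration slide whose
#'   only bright minority are the deposition spots) and every acquired
#'   pixel is returned as foreground.
#' @return Logical rows x cols matrix (TRUE = tissue).
#' @export
segment_tissue <- function(dataset, closing_radius = 2L,
                           min_tissue_fraction = 0.2) {
  tic <- total_ion_current(dataset)
  lv <- log10(tic$values + 1)
  ok <- !is.na(lv)
  rng <- range(lv[ok])
  if (diff(rng) < .Machine$double.eps^0.5) {
    # no contrast: uniform slide, everything is foreground
    return(ok)
  }
  scaled <- (lv - rng[1L]) / diff(rng)
  scaled[!ok] <- 0
  thr <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
  mask <- scaled > thr & ok
  if (!any(mask)) {
    warning("no tissue found: all-background slide")
    return(mask)
  }
  if (mean(mask[ok]) < min_tissue_fraction) {
    # bright pixels are a small minority: uniformly coated slide, the
    # threshold separated deposition spots rather than tissue from glass
    return(ok)
  }
  # closing bridges small gaps; odd-sized disc brush
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
  closed <- EBImage::closing(EBImage::Image(t(mask * 1)), brush)
  mask <- t(EBImage::imageData(closed)) > 0.5 & ok
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  labs <- t(EBImage::imageData(lab))
  tab <- table(labs[labs > 0])
  if (length(tab) == 0L) {
    warning("no tissue found: all-background slide")
    return(matrix(FALSE, nrow(lv), ncol(lv)))
  }
  keep <- as.integer(names(tab)[which.max(tab)])
  labs == keep
}

#' Classify pixels into background and signal populations
#'
#' One-dimensional two-means clustering of log10 intensities (Lloyd's
#' algorithm, deterministically initialized at the 10th and 90th
#' percentiles); the lower-mean cluster is the background population.
#' Constant input degenerates to a single all-background cluster with a
#' warning.
#'
#' @param log_image a [log_ion_image()].
#' @param mask logical matrix restricting the pixels considered (default:
#'   every non-missing pixel).
#' @return A list with logical matrices `background` and `signal`, and
#'   numeric `means = c(background, signal)` (signal mean `NA` in the
#'   degenerate case).
#' @export
classify_background <- function(log_image, mask = NULL) {
  stopifnot(inherits(log_image, "log_ion_image"))
  v <- log_image$values
  if (is.null(mask)) mask <- !is.na(v)
  sel <- mask & !is.na(v)
  x <- v[sel]
  if (length(x) < 2L) stop("need at least 2 pixels to classify")
  background <- matrix(FALSE, nrow(v), ncol(v))
  signal <- matrix(FALSE, nrow(v), ncol(v))
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    warning("constant intensities: single-cluster fallback, all background")
    background[sel] <- TRUE
    return(list(background = background, signal = signal,
                means = c(background = mean(x), signal = NA_real_)))
  }
  centers <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  if (centers[1L] == centers[2L]) {
    centers <- range(x)
  }
  km <- stats::kmeans(x, centers = matrix(centers, ncol = 1),
                      algorithm = "Lloyd", iter.max = 100L)
  lo <- which.min(km$centers)
  is_bg <- km$cluster == lo
  background[sel] <- is_bg
  signal[sel] <- !is_bg
  list(background = background, signal = signal,
       means = c(background = km$centers[lo],
                 signal = km$centers[-lo][1L]))
}

#' Mode of a log-intensity distribution
#'
#' Argmax of a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth, evaluated on a fixed 512-point grid spanning
#' the data range.
#'
#' @param values numeric vector of log10 intensities (at least 10 values).
#' @param n_grid grid size of the density evaluation.
#' @return The mode (a single number).
#' @export
estimate_mode <- function(values, n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values to estimate a mode")
  if (diff(range(values)) < .Machine$double.eps^0.5) return(values[1L])
  d <- stats::density(values, bw = "nrd0", n = n_grid,
                      from = min(values), to = max(values))
  d$x[which.max(d$y)]
}

#' Background model of one ion channel of one sample
#'
#' @param log_image a [log_ion_image()].
#' @param mask optional logical matrix restricting the pixels used.
#' @param mode_on one of `"all"` (default; the density mode over every
#'   pixel of the sample, relying on background dominance) or
#'   `"background"` (mode over the background cluster only).
#' @param quantile quantile level later used for the noise threshold.
#' @return A list of class `background_model` with `background_mode`,
#'   `background_mean` (mean of the low-intensity cluster),
#'   `cluster_means`, and `quantile`.
#' @export
background_model <- function(log_image, mask = NULL,
                             mode_on = c("all", "background"),
                             quantile = 0.995) {
  mode_on <- match.arg(mode_on)
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  cl <- classify_background(log_image, mask)
  v <- log_image$values
  pool <- if (mode_on == "all") {
    if (is.null(mask)) v[!is.na(v)] else v[mask & !is.na(v)]
  } else {
    v[cl$background]
  }
  structure(
    list(background_mode = estimate_mode(pool),
         background_mean = unname(cl$means["background"]),
         cluster_means = cl$means,
         quantile = quantile,
         mode_on = mode_on),
    class = "background_model")
}

#' Batch-correct a log ion image
#'
#' Subtracts the sample's background density mode from every pixel, which
#' in practical terms sets the mean background intensity to zero and makes
#' samples acquired in different runs comparable.  A per-sample monotone
#' shift: within-sample pixel ranking is unchanged.
#'
#' @param log_image a [log_ion_image()].
#' @param model the sample's [background_model()].
#' @return The corrected [log_ion_image()].
#' @export
batch_correct <- function(log_image, model) {
  stopifnot(inherits(log_image, "log_ion_image"),
            inherits(model, "background_model"))
  out <- log_image
  out$values <- log_image$values - model$background_mode
  out
}

#' Noise threshold from pooled corrected control pixels
#'
#' Empirical quantile (default level 0.995) of the corrected log10
#' intensities pooled over untreated control samples; pixels above it are
#' taken to carry true signal.
#'
#' @param control_values numeric vector of corrected control intensities.
#' @param quantile quantile level, default 0.995.
#' @return The threshold (log10 units).
#' @export
estimate_noise_threshold <- function(control_values, quantile = 0.995) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0L) stop("empty control pixel pool")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  stats::quantile(control_values, quantile, names = FALSE)
}

#' Above-noise pixel mask
#'
#' Flags pixels that are on tissue and strictly above the noise threshold;
#' ties at the threshold count as background.
#'
#' @param corrected a corrected [log_ion_image()].
#' @param threshold noise threshold (log10 units).
#' @param tissue logical tissue mask.
#' @return Logical rows x cols matrix.
#' @export
above_noise_mask <- function(corrected, threshold, tissue) {
  stopifnot(inherits(corrected, "log_ion_image"), !is.na(threshold))
  v <- corrected$values
  m <- !is.na(v) & tissue & v > threshold
  m
}

#' Pixel masks of a processed section
#'
#' Bundles the tissue, above-noise and background masks with their
#' consistency guarantees (above-noise pixels are on tissue; background and
#' above-noise are disjoint).
#'
#' @param tissue,above_noise,background logical matrices.
#' @return A list of class `pixel_masks`.
#' @export
pixel_masks <- function(tissue, above_noise, background) {
  stopifnot(identical(dim(tissue), dim(above_noise)),
            identical(dim(tissue), dim(background)))
  if (any(above_noise & !tissue)) {
    stop("above-noise pixels must lie inside the tissue mask")
  }
  if (any(above_noise & background)) {
    stop("a pixel cannot be both background and above-noise")
  }
  structure(list(tissue = tissue, above_noise = above_noise,
                 background = background),
            class = "pixel_masks")
}

#' Run the per-sample preprocessing chain for one ion
#'
#' Extracts the ion image, log-transforms it, estimates the background
#' model on tissue pixels and subtracts the density mode.  The noise
#' threshold is a cross-sample quantity (pooled controls) and is applied
#' separately via [above_noise_mask()].
#'
#' @param dataset an [msi_dataset()].
#' @param target_mz ion to process (3618 or 3886 in this workflow).
#' @param tolerance extraction half-width in Da.
#' @param pseudocount for the log transform.
#' @param tissue optional precomputed tissue mask (else segmented here).
#' @param mode_on passed to [background_model()].
#' @return A list with `corrected` ([log_ion_image()]), `model`
#'   ([background_model()]), and `tissue` (logical matrix).
#' @export
preprocess_ion <- function(dataset, target_mz, tolerance = 1,
                           pseudocount = 1, tissue = NULL,
                           mode_on = "all") {
  img <- extract_ion_image(dataset, target_mz, tolerance)
  lg <- log_transform(img, pseudocount)
  if (is.null(tissue)) tissue <- segment_tissue(dataset)
  # the background model pools ALL acquired pixels of the slide (not
  # tissue-only): on a strongly treated section the tissue pixels are
  # dominated by signal and their density mode would sit on the signal
  # peak, not the background
  model <- background_model(lg, mask = NULL, mode_on = mode_on)
  list(corrected = batch_correct(lg, model), model = model, tissue = tissue)
}

#' Serialize a background model to JSON
#' @param model a [background_model()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_background_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
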