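# Quantitative calibration.  Four preprocessing steps per slide:
# (1) two-population clustering of log10 SP-C analog intensities; the mean
#     of the low-intensity (background) cluster is subtracted to compensate
#     sample-to-sample analytical variability;
# (2) the melittin marker channel identifies the pixels actually spotted;
# (3) the spotted amount per pixel (c_pixel, ng) is the nominal spot
#     nanograms divided by the spot's pixel count;
# (4) a linear mixed model (random intercept per experiment, REML) relates
#     the per-spot mean adjusted log10 signal to c_pixel.
# Inverse prediction then converts corrected tissue images into absolute
# ng-per-pixel maps with 95% confidence bounds.

#' Detect calibration spots from the melittin marker channel
#'
#' Splits the melittin log10 intensities into two populations (two-means,
#' deterministic initialization) and takes the connected components of the
#' upper population, ranked by size.
#'
#' @param melittin_image [ion_image()] of the melittin channel.
#' @param expected_n number of spots that must be found.
#' @param pseudocount for the log transform.
#' @param min_separation minimum distance between the two cluster means
#'   (log10 units) for the upper cluster to count as true marker signal;
#'   below it the channel is background-only (the marker is deposited at
#'   ~100x background, so 0.5 = about a 3-fold intensity step is lenient).
#' @return List of `expected_n` logical pixel-set matrices, largest first.
#' @export
detect_spots <- function(melittin_image, expected_n, pseudocount = 1,
                         min_separation = 0.5) {
  if (expected_n < 1L) stop("expected_n must be >= 1")
  lg <- log_transform(melittin_image, pseudocount)
  cl <- classify_background(lg)
  sep <- unname(cl$means["signal"] - cl$means["background"])
  if (!any(cl$signal) || is.na(sep) || sep < min_separation) {
    stop("no above-background melittin signal found (0 spots, expected ",
         expected_n, ")")
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(cl$signal * 1)))
  labs <- t(EBImage::imageData(lab))
  tab <- sort(table(labs[labs > 0]), decreasing = TRUE)
  if (length(tab) < expected_n) {
    stop("found only ", length(tab), " melittin spot component(s), expected ",
         expected_n, " (touching spots merge into one component)")
  }
  if (length(tab) > expected_n) {
    warning("found ", length(tab), " melittin components, keeping the ",
            expected_n, " largest")
  }
  keep <- as.integer(names(tab)[seq_len(expected_n)])
  lapply(keep, function(k) labs == k)
}

#' Subtract the slide's background-cluster mean
#'
#' Step 1 of the calibration preprocessing: the mean log10 intensity of the
#' low-intensity population is removed from every pixel of the slide.
#'
#' @param log_image a [log_ion_image()].
#' @param background_mean mean of the background cluster (from
#'   [classify_background()] or [background_model()]).
#' @return Adjusted [log_ion_image()].
#' @export
spot_background_subtract <- function(log_image, background_mean) {
  stopifnot(inherits(log_image, "log_ion_image"), is.finite(background_mean))
  out <- log_image
  out$values <- log_image$values - background_mean
  out
}

#' Build the calibration table from a set of slides
#'
#' Runs steps 1-3 on every slide: background-cluster subtraction on the
#' analyte channel, melittin spot detection, and per-spot `c_pixel` and
#' mean adjusted signal.  Spots are assigned to nominal amounts by the
#' known stamp layout (left-to-right, top-to-bottom in increasing amount),
#' never by intensity.
#'
#' @param slides list of calibration [msi_dataset()]s.
#' @param amounts ng per spot in stamp order.
#' @param experiment_ids,replicate_ids vectors parallel to `slides`; by
#'   default read from the slides' `truth` attribute when present.
#' @param target_mz analyte channel (default the SP-C analog adduct, 3618).
#' @param melittin_mz marker channel.
#' @param tolerance extraction half-width (Da).
#' @param pseudocount for log transforms.
#' @return A tibble with one row per spot per slide: `experiment_id`,
#'   `replicate_id`, `amount_ng`, `n_pixels`, `c_pixel`, `mean_signal`.
#' @export
build_calibration_table <- function(slides, amounts,
                                    experiment_ids = NULL,
                                    replicate_ids = NULL,
                                    target_mz = 3618, melittin_mz = 2846,
                                    tolerance = 1, pseudocount = 1) {
  if (length(slides) == 0L) stop("no calibration slides supplied")
  if (is.null(experiment_ids)) {
    experiment_ids <- vapply(slides, function(s) {
      tr <- attr(s, "truth")
      if (!is.null(tr$experiment)) as.integer(tr$experiment) else NA_integer_
    }, integer(1))
  }
  if (is.null(replicate_ids)) {
    replicate_ids <- vapply(slides, function(s) {
      tr <- attr(s, "truth")
      if (!is.null(tr$replicate)) as.integer(tr$replicate) else NA_integer_
    }, integer(1))
  }
  if (anyNA(experiment_ids)) {
    stop("experiment_ids must be supplied when slides carry no truth attribute")
  }
  rows <- list()
  for (i in seq_along(slides)) {
    sl <- slides[[i]]
    analyte <- log_transform(extract_ion_image(sl, target_mz, tolerance),
                             pseudocount)
    mel <- extract_ion_image(sl, melittin_mz, tolerance)
    spots <- detect_spots(mel, expected_n = length(amounts),
                          pseudocount = pseudocount)
    # two-population clustering over all pixels draws the boundary between
    # signal and background; the background average is then taken over
    # background-cluster pixels outside the melittin-marked deposition
    # areas.  Clustering off-spot pixels alone would split the background
    # Gaussian itself (lower half-mean, ~0.8 sigma low); averaging the raw
    # background cluster would let low-concentration standards leak in and
    # inflate it.
    off_spot <- !Reduce(`|`, spots)
    cl <- classify_background(analyte)
    bg_px <- cl$background & off_spot & !is.na(analyte$values)
    bg_mean <- if (any(bg_px)) mean(analyte$values[bg_px]) else
      unname(cl$means["background"])
    adj <- spot_background_subtract(analyte, bg_mean)
    # assignment by stamp layout: order components by centroid position
    # (row band, then column), matching the increasing-amount stamp order
    cent <- t(vapply(spots, function(m) {
      w <- which(m, arr.ind = TRUE)
      c(y = mean(w[, 1L]), x = mean(w[, 2L]))
    }, numeric(2)))
    band_height <- max(cent[, "y"]) - min(cent[, "y"])
    band <- if (band_height < 1e-9) rep(1L, nrow(cent)) else {
      # cluster centroid rows into bands via gaps larger than half the span
      o <- order(cent[, "y"])
      b <- cumsum(c(1, diff(cent[o, "y"]) > band_height / 2))
      b[order(o)]
    }
    ord <- order(band, cent[, "x"])
    spots <- spots[ord]
    for (s in seq_along(amounts)) {
      m <- spots[[s]]
      vals <- adj$values[m]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        stop("slide ", i, ", spot ", s, ": no acquired pixels")
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment_id = experiment_ids[i],
        replicate_id = replicate_ids[i],
        amount_ng = amounts[s],
        n_pixels = sum(m),
        c_pixel = amounts[s] / sum(m),
        mean_signal = mean(vals))
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit the mixed-effects calibration curve
#'
#' Linear mixed model `mean_signal ~ c_pixel + (1 | experiment_id)` fitted
#' by REML; 95% confidence intervals on the fixed effects use Satterthwaite
#' degrees of freedom (with as few as 3 experiments, normal-quantile Wald
#' intervals on the intercept undercover).  A singular fit (zero estimated
#' between-experiment variance) falls back to pooled ordinary least squares
#' with a warning.
#'
#' @param table calibration table from [build_calibration_table()].
#' @return A list of class `calibration_fit`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci` (95%), `exp_var`, `residual_var`, `method`
#'   (`"lmm"` or `"ols"`), and the fitted model object.
#' @export
fit_calibration <- function(table) {
  stopifnot(all(c("experiment_id", "c_pixel", "mean_signal") %in%
                  names(table)))
  n_exp <- length(unique(table$experiment_id))
  if (n_exp < 2L) {
    stop("need at least 2 experiments for the mixed-effects fit (got ",
         n_exp, ")")
  }
  if (length(unique(table$amount_ng %||% table$c_pixel)) < 3L) {
    stop("need at least 3 distinct amounts")
  }
  fit <- suppressMessages(lmerTest::lmer(
    mean_signal ~ c_pixel + (1 | experiment_id), data = table, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular mixed-effects fit (zero between-experiment variance); ",
            "falling back to pooled ordinary regression")
    ols <- stats::lm(mean_signal ~ c_pixel, data = table)
    ci <- stats::confint(ols, level = 0.95)
    est <- stats::coef(ols)
    return(structure(
      list(slope = unname(est["c_pixel"]),
           intercept = unname(est["(Intercept)"]),
           slope_ci = unname(ci["c_pixel", ]),
           intercept_ci = unname(ci["(Intercept)", ]),
           exp_var = 0,
           residual_var = stats::sigma(ols)^2,
           method = "ols", model = ols),
      class = "calibration_fit"))
  }
  cf <- stats::coef(summary(fit))  # Estimate, SE, df (Satterthwaite), t, p
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  df <- cf[, "df"]
  tq <- stats::qt(0.975, df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(slope = unname(est["c_pixel"]),
         intercept = unname(est["(Intercept)"]),
         slope_ci = unname(c(est["c_pixel"] - tq["c_pixel"] * se["c_pixel"],
                             est["c_pixel"] + tq["c_pixel"] * se["c_pixel"])),
         intercept_ci = unname(c(
           est["(Intercept)"] - tq["(Intercept)"] * se["(Intercept)"],
           est["(Intercept)"] + tq["(Intercept)"] * se["(Intercept)"])),
         exp_var = vc$vcov[vc$grp == "experiment_id"],
         residual_var = vc$vcov[vc$grp == "Residual"],
         method = "lmm", model = fit),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> log10 signal = %.3f * c_pixel + %.3f  [%s]\n",
    x$slope, x$intercept, x$method))
  cat(sprintf("  slope 95%% CI: [%.3f, %.3f]  intercept 95%% CI: [%.3f, %.3f]\n",
              x$slope_ci[1], x$slope_ci[2],
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  between-experiment var: %.4g  residual var: %.4g\n",
              x$exp_var, x$residual_var))
  invisible(x)
}

#' Quantify a corrected ion image in absolute nanograms per pixel
#'
#' Inverts the calibration curve per above-noise pixel:
#' `amount = (signal - intercept) / slope`.  The 95% bounds invert the
#' fixed-effect confidence envelope: for each pixel the lower bound is the
#' smallest and the upper bound the largest amount over the four
#' slope/intercept CI corner combinations.  Signals below the intercept
#' clamp to 0 ng and are flagged.  Below-noise pixels are undefined (`NA`).
#'
#' @param corrected corrected [log_ion_image()].
#' @param fit a [calibration_fit()] with positive slope.
#' @param mask logical above-noise matrix.
#' @return A list of class `quant_map`: matrices `amount`, `amount_lo`,
#'   `amount_hi` (ng per pixel) and logical `clamped`.
#' @export
quantify <- function(corrected, fit, mask) {
  stopifnot(inherits(corrected, "log_ion_image"),
            inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) stop("calibration slope must be positive")
  v <- corrected$values
  use <- mask & !is.na(v)
  amount <- amount_lo <- amount_hi <- matrix(NA_real_, nrow(v), ncol(v))
  clamped <- matrix(FALSE, nrow(v), ncol(v))
  s <- v[use]
  est <- (s - fit$intercept) / fit$slope
  clamp <- est < 0
  est[clamp] <- 0
  corners <- expand.grid(slope = fit$slope_ci, intercept = fit$intercept_ci)
  cand <- vapply(seq_len(nrow(corners)), function(i) {
    pmax((s - corners$intercept[i]) / corners$slope[i], 0)
  }, numeric(length(s)))
  if (length(s) == 1L) cand <- matrix(cand, nrow = 1L)
  amount[use] <- est
  amount_lo[use] <- apply(cand, 1L, min)
  amount_hi[use] <- apply(cand, 1L, max)
  clamped[use] <- clamp
  structure(list(amount = amount, amount_lo = amount_lo,
                 amount_hi = amount_hi, clamped = clamped,
                 sample_id = corrected$sample_id),
            class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  def <- !is.na(x$amount)
  cat(sprintf("<quant_map> %s: %d quantified pixels", x$sample_id, sum(def)))
  if (any(def)) {
    cat(sprintf(", median %.3g ng/pixel (%d clamped to 0)",
                stats::median(x$amount[def]), sum(x$clamped)))
  }
  cat("\n")
  invisible(x)
}

#' Run the full calibration pipeline on a set of slides
#'
#' Convenience wrapper: builds the calibration table (steps 1-3) and fits
#' the mixed model (step 4).
#'
#' @inheritParams build_calibration_table
#' @return A list with `table` and `fit`.
#' @export
run_calibration <- function(slides, amounts, target_mz = 3618,
                            melittin_mz = 2846, tolerance = 1) {
  tab <- build_calibration_table(slides, amounts, target_mz = target_mz,
                                 melittin_mz = melittin_mz,
                                 tolerance = tolerance)
  list(table = tab, fit = fit_calibration(tab))
}

#' Serialize a calibration fit to JSON
#' @param fit a `calibration_fit`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_calibration_fit <- function(fit, path) {
  jsonlite::write_json(
    fit[c("slope", "intercept", "slope_ci", "intercept_ci",
          "exp_var", "residual_var", "method")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
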