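# Synthetic-data generators.  These emulate the statistical structure the
# analysis assumes -- not MALDI physics: spectra are sparse peak lists with
# a lognormal background (normal on the log10 scale), peptide channels at
# m/z 3618 (SP-C analog + Na) and 3886 (SP-B analog + H), an additive
# per-sample batch offset on the log10 scale, a radial attenuation of the
# peptide signal towards the tissue border, and a handful of hotspots of
# local accumulation.  Calibration slides follow the six-point 1-50 ng
# design with a 6.25 ng melittin deposition marker.

MZ_SPC <- 3618      # [SP-C analog + Na]+ adduct
MZ_SPB <- 3886      # [SP-B analog + H]+
MZ_MELITTIN <- 2846 # [melittin + H]+ (simulation marker channel)

# evaluate code under a fixed seed without disturbing the caller's RNG
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Parameters for a synthetic lung-section MSI dataset
#'
#' Defaults describe a treated section: an elliptical tissue phantom on a
#' 50 x 50 grid at 350 um pitch, SP-C analog signal 10^log10(sp_ratio)
#' times stronger than SP-B analog (the formulation carries 1.5% SP-C
#' analog vs 0.2% SP-B analog by mass), mild radial attenuation towards
#' the border and three hotspots of central accumulation.  Setting
#' `abundance_scale = 0` gives an untreated control section whose peptide
#' channels carry background only.
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param pixel_pitch raster step in micrometres.
#' @param tissue_phantom list with `semiaxes` (fractions of the half-grid,
#'   length 2) and optional `holes` (list of `c(row_frac, col_frac,
#'   radius_frac)` circles cut out of the ellipse).
#' @param sp_ratio SP-C:SP-B analog intensity ratio (default 7.5 = 1.5/0.2).
#' @param base_log10 log10 intensity of the SP-C analog signal at unit
#'   abundance at the section centre (arbitrary units).
#' @param abundance_scale multiplies the raw-scale peptide signal; 0 means
#'   an untreated control section.
#' @param signal_sigma SD of the per-pixel peptide signal on the log10 scale.
#' @param radial_decay log10 attenuation per pixel of distance from the
#'   section centre.
#' @param n_hotspots number of local-accumulation foci.
#' @param hotspot_boost,hotspot_radius log10 gain at a hotspot centre and
#'   its Gaussian radius in pixels.
#' @param background_mu,background_sigma mean and SD of the log10 background
#'   intensity (lognormal background on the raw scale).
#' @param batch_offset per-sample additive shift on the log10 scale, applied
#'   to every intensity in the sample.
#' @param n_decoys number of decoy matrix peaks added to each spectrum.
#' @param seed integer seed; identical parameters and seed give
#'   byte-identical output.
#' @param sample_id,group identifiers attached to the dataset.
#' @return A list of class `section_sim_params`.
#' @export
section_sim_params <- function(grid_shape = c(50L, 50L),
                               pixel_pitch = 350,
                               tissue_phantom = list(semiaxes = c(0.80, 0.70)),
                               sp_ratio = 7.5,
                               base_log10 = 2.5,
                               abundance_scale = 1,
                               signal_sigma = 0.25,
                               radial_decay = 0.015,
                               n_hotspots = 3L,
                               hotspot_boost = 0.5,
                               hotspot_radius = 3,
                               background_mu = 0,
                               background_sigma = 0.15,
                               batch_offset = 0,
                               n_decoys = 5L,
                               seed = 1L,
                               sample_id = "synthetic_section",
                               group = if (abundance_scale > 0) "treated" else "control") {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L)) {
    stop("grid_shape must be two positive integers")
  }
  if (background_sigma <= 0) stop("background_sigma must be > 0")
  if (sp_ratio <= 0) stop("sp_ratio must be > 0")
  if (abundance_scale < 0) stop("abundance_scale must be >= 0")
  if (is.null(tissue_phantom$semiaxes) || length(tissue_phantom$semiaxes) != 2L) {
    stop("tissue_phantom must supply two semiaxes")
  }
  if (any(tissue_phantom$semiaxes > 1) || any(tissue_phantom$semiaxes <= 0)) {
    stop("phantom semiaxes must lie in (0, 1] of the half-grid; ",
         "a phantom larger than the grid is invalid")
  }
  structure(
    list(grid_shape = grid_shape, pixel_pitch = pixel_pitch,
         tissue_phantom = tissue_phantom, sp_ratio = sp_ratio,
         base_log10 = base_log10, abundance_scale = abundance_scale,
         signal_sigma = signal_sigma, radial_decay = radial_decay,
         n_hotspots = as.integer(n_hotspots), hotspot_boost = hotspot_boost,
         hotspot_radius = hotspot_radius,
         background_mu = background_mu, background_sigma = background_sigma,
         batch_offset = batch_offset, n_decoys = as.integer(n_decoys),
         seed = as.integer(seed), sample_id = sample_id, group = group),
    class = "section_sim_params")
}

ellipse_mask <- function(grid_shape, phantom) {
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
  ay <- phantom$semiaxes[1L] * rows / 2
  ax <- phantom$semiaxes[2L] * cols / 2
  yy <- matrix(seq_len(rows) - 1, rows, cols)
  xx <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
  mask <- ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
  for (h in phantom$holes %||% list()) {
    hy <- h[1L] * (rows - 1); hx <- h[2L] * (cols - 1)
    hr <- h[3L] * min(rows, cols)
    mask <- mask & ((yy - hy)^2 + (xx - hx)^2 > hr^2)
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# decoy matrix-cluster m/z channels, kept >= 5 Da away from analyte channels
decoy_mz <- function(n, avoid = c(MZ_SPC, MZ_SPB, MZ_MELITTIN)) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- runif(1, 1250, 3500)
    if (all(abs(cand - c(avoid, out)) >= 5)) out <- c(out, cand)
  }
  sort(out)
}

# assemble per-pixel sparse peak lists from a channel intensity matrix
# (n_pixels x n_channels) and channel m/z values; a small per-pixel m/z
# jitter (< 0.35 Da) emulates TOF mass-measurement scatter
assemble_pixels <- function(channel_mz, channel_int, jitter_sd = 0.1) {
  n <- nrow(channel_int)
  k <- length(channel_mz)
  jit <- matrix(pmax(pmin(rnorm(n * k, 0, jitter_sd), 0.35), -0.35), n, k)
  mz_mat <- matrix(channel_mz, n, k, byrow = TRUE) + jit
  mz_list <- vector("list", n)
  int_list <- vector("list", n)
  for (i in seq_len(n)) {
    o <- order(mz_mat[i, ])
    mz_list[[i]] <- mz_mat[i, o]
    int_list[[i]] <- channel_int[i, o]
  }
  list(mz = mz_list, intensity = int_list)
}

#' Generate a synthetic lung-section MSI dataset
#'
#' Off-tissue pixels carry lognormal background only; on-tissue pixels of a
#' treated section additionally carry the peptide signal, attenuated with
#' distance from the section centre and boosted at hotspot foci.  The batch
#' offset shifts every intensity of the sample on the log10 scale.  The
#' returned dataset carries a `truth` attribute (tissue mask, true signal
#' masks and per-pixel true signal) used by tests.
#'
#' @param params a [section_sim_params()].
#' @return An [msi_dataset()] with attribute `truth`.
#' @export
generate_section <- function(params) {
  stopifnot(inherits(params, "section_sim_params"))
  with_preserved_seed(params$seed, {
    rows <- params$grid_shape[1L]; cols <- params$grid_shape[2L]
    tissue <- ellipse_mask(params$grid_shape, params$tissue_phantom)
    yy <- matrix(seq_len(rows) - 1, rows, cols)
    xx <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
    cy <- (rows - 1) / 2; cx <- (cols - 1) / 2
    d_center <- sqrt((yy - cy)^2 + (xx - cx)^2)

    n <- rows * cols
    px <- as.vector(xx); py <- as.vector(yy)
    on_tissue <- as.vector(tissue)

    # hotspot foci among tissue pixels
    hs_boost <- numeric(n)
    hs_centers <- NULL
    if (params$n_hotspots > 0L && any(on_tissue)) {
      idx <- sample(which(on_tissue), params$n_hotspots)
      hs_centers <- cbind(x = px[idx], y = py[idx])
      for (j in seq_len(nrow(hs_centers))) {
        d2 <- (px - hs_centers[j, "x"])^2 + (py - hs_centers[j, "y"])^2
        hs_boost <- hs_boost +
          params$hotspot_boost * exp(-d2 / (2 * params$hotspot_radius^2))
      }
    }

    ions <- data.frame(
      ion = c("SP-C analog", "SP-B analog"),
      mz = c(MZ_SPC, MZ_SPB),
      base_log10 = c(params$base_log10,
                     params$base_log10 - log10(params$sp_ratio)))

    dmz <- decoy_mz(params$n_decoys)
    channel_mz <- c(ions$mz, dmz)
    k <- length(channel_mz)
    raw <- matrix(0, n, k)
    true_sig <- vector("list", nrow(ions))
    names(true_sig) <- ions$ion

    for (j in seq_len(nrow(ions))) {
      bg <- 10^rnorm(n, params$background_mu, params$background_sigma)
      sig <- numeric(n)
      if (params$abundance_scale > 0) {
        mu <- ions$base_log10[j] + log10(params$abundance_scale) -
          params$radial_decay * as.vector(d_center) + hs_boost
        sig[on_tissue] <- 10^(mu[on_tissue] +
                                rnorm(sum(on_tissue), 0, params$signal_sigma))
      }
      raw[, j] <- bg + sig
      true_sig[[j]] <- matrix(log10(ifelse(sig > 0, sig, NA)), rows, cols)
    }
    # decoy channels: background plus a tissue-dependent matrix component,
    # giving the total ion current its tissue contrast
    for (j in seq_along(dmz)) {
      bg <- 10^rnorm(n, params$background_mu, params$background_sigma)
      tis <- ifelse(on_tissue, 10^rnorm(n, params$background_mu + 1.2, 0.3), 0)
      raw[, j + nrow(ions)] <- bg + tis
    }
    raw <- raw * 10^params$batch_offset

    pk <- assemble_pixels(channel_mz, raw)
    ds <- msi_dataset(data.frame(x = px, y = py), pk$mz, pk$intensity,
                      grid_shape = params$grid_shape,
                      pixel_pitch = params$pixel_pitch,
                      sample_id = params$sample_id, group = params$group)
    attr(ds, "truth") <- list(
      tissue = tissue,
      signal = matrix(on_tissue & params$abundance_scale > 0, rows, cols),
      true_signal_log10 = true_sig,
      hotspots = hs_centers,
      d_center = d_center,
      params = params)
    ds
  })
}

#' Parameters for synthetic calibration slides
#'
#' Defaults mirror the study's calibration design: six 0.5 ul spots of
#' 1, 2.5, 5, 10, 25 and 50 ng of both peptides plus 6.25 ng of melittin as
#' a deposition marker, prepared as three independent experiments with two
#' replicate slides each, fitted as log10 signal = slope * c_pixel +
#' intercept with a random intercept per experiment (generating values
#' slope 3.1, intercept 0.2).
#'
#' @param amounts ng per spot, strictly increasing and positive.
#' @param melittin_amount ng of melittin per spot.
#' @param n_experiments,n_replicates experiments and replicate slides per
#'   experiment.
#' @param slope,intercept generating fixed effects (log10 intensity per ng;
#'   log10 intensity).
#' @param exp_sd SD of the between-experiment random intercept (log10).
#' @param pixel_sd residual SD of the per-pixel log10 signal.
#' @param batch_sd SD of the per-slide batch offset applied to all
#'   intensities of a slide (removed by background subtraction downstream).
#' @param spot_radius spot radius in pixels.
#' @param grid_shape slide grid `c(rows, cols)`.
#' @param background_mu,background_sigma log10 background parameters of the
#'   homogenate-coated slide.  Spot signals ride on `background_mu`: the
#'   per-pixel log10 mean inside a spot is `background_mu + slope * c_pixel
#'   + intercept` (plus random effects), because the calibration curve is
#'   defined on the background-subtracted scale -- the slide's mean
#'   background level is exactly what the downstream background-cluster
#'   subtraction removes.  With `background_mu = 0` and all SDs zero the
#'   stamped log10 signal is exactly `slope * c_pixel + intercept`.
#' @param melittin_log10,melittin_sigma melittin marker signal level above
#'   the slide background (log10 scale) and its SD inside spots.
#' @param seed integer seed.
#' @return A list of class `calib_sim_params`.
#' @export
calib_sim_params <- function(amounts = c(1, 2.5, 5, 10, 25, 50),
                             melittin_amount = 6.25,
                             n_experiments = 3L,
                             n_replicates = 2L,
                             slope = 3.1,
                             intercept = 0.2,
                             exp_sd = 0.05,
                             pixel_sd = 0.10,
                             batch_sd = 0.15,
                             spot_radius = 3,
                             grid_shape = c(30L, 48L),
                             background_mu = 2,
                             background_sigma = 0.10,
                             melittin_log10 = 2.0,
                             melittin_sigma = 0.10,
                             seed = 1L) {
  if (any(diff(amounts) <= 0) || any(amounts <= 0)) {
    stop("amounts must be strictly increasing and positive")
  }
  if (slope <= 0) stop("slope must be > 0")
  if (exp_sd < 0 || pixel_sd < 0 || batch_sd < 0) stop("SDs must be >= 0")
  structure(
    list(amounts = amounts, melittin_amount = melittin_amount,
         n_experiments = as.integer(n_experiments),
         n_replicates = as.integer(n_replicates),
         slope = slope, intercept = intercept,
         exp_sd = exp_sd, pixel_sd = pixel_sd, batch_sd = batch_sd,
         spot_radius = spot_radius, grid_shape = as.integer(grid_shape),
         background_mu = background_mu, background_sigma = background_sigma,
         melittin_log10 = melittin_log10, melittin_sigma = melittin_sigma,
         seed = as.integer(seed)),
    class = "calib_sim_params")
}

# default spot centres: two rows of ceiling(n/2) spots, evenly spaced
spot_centers <- function(n_spots, grid_shape, radius) {
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  ncol_s <- ceiling(n_spots / 2)
  nrow_s <- if (n_spots > 1L) 2L else 1L
  cxs <- round(seq(cols / (ncol_s + 1), cols * ncol_s / (ncol_s + 1),
                   length.out = ncol_s))
  cys <- round(seq(rows / (nrow_s + 1), rows * nrow_s / (nrow_s + 1),
                   length.out = nrow_s))
  centers <- expand.grid(x = cxs, y = cys)[seq_len(n_spots), , drop = FALSE]
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  if (min(d) <= 2 * radius) {
    stop("spot placement overlaps: grid too small for ", n_spots,
         " spots of radius ", radius)
  }
  if (any(centers$x - radius < 0) || any(centers$x + radius >= cols) ||
      any(centers$y - radius < 0) || any(centers$y + radius >= rows)) {
    stop("spot placement exceeds the slide grid")
  }
  centers
}

#' Generate one synthetic calibration slide
#'
#' Spot pixels carry the SP-C analog channel at per-pixel log10 mean
#' `slope * c_pixel + intercept` plus the experiment random effect and the
#' slide batch offset, with residual SD `pixel_sd`; `c_pixel` is the spot's
#' nanograms divided by its pixel count.  The melittin channel marks the
#' spotted pixels.  Off-spot pixels carry homogenate background in every
#' channel.  The experiment random effect is shared by both replicate
#' slides of an experiment.
#'
#' @param params a [calib_sim_params()].
#' @param experiment,replicate 1-based indices.
#' @return An [msi_dataset()] (group `"calibration"`) with attribute `truth`
#'   (spot masks, amounts, `c_pixel`, the experiment effect, batch offset).
#' @export
generate_calibration_slide <- function(params, experiment = 1L, replicate = 1L) {
  stopifnot(inherits(params, "calib_sim_params"))
  if (experiment < 1L || experiment > params$n_experiments) {
    stop("experiment index out of range")
  }
  if (replicate < 1L || replicate > params$n_replicates) {
    stop("replicate index out of range")
  }
  # experiment effect must be identical across replicates: own seed stream
  exp_eff <- with_preserved_seed(params$seed + 7919L * experiment,
                                 rnorm(1, 0, params$exp_sd))
  with_preserved_seed(params$seed + 7919L * experiment + 131L * replicate, {
    rows <- params$grid_shape[1L]; cols <- params$grid_shape[2L]
    n <- rows * cols
    yy <- matrix(seq_len(rows) - 1, rows, cols)
    xx <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
    px <- as.vector(xx); py <- as.vector(yy)

    n_spots <- length(params$amounts)
    centers <- spot_centers(n_spots, params$grid_shape, params$spot_radius)
    spot_masks <- vector("list", n_spots)
    spot_of <- integer(n)  # 0 = off-spot
    for (s in seq_len(n_spots)) {
      m <- (px - centers$x[s])^2 + (py - centers$y[s])^2 <=
        params$spot_radius^2
      spot_masks[[s]] <- matrix(m, rows, cols)
      spot_of[m] <- s
    }
    c_pixel <- params$amounts / vapply(spot_masks, sum, numeric(1))

    batch <- rnorm(1, 0, params$batch_sd)

    # SP-C analog channel; spot signal rides on the slide background level
    spc <- 10^rnorm(n, params$background_mu, params$background_sigma)
    on_spot <- spot_of > 0L
    spc[on_spot] <- 10^(params$background_mu +
                          params$slope * c_pixel[spot_of[on_spot]] +
                          params$intercept + exp_eff +
                          rnorm(sum(on_spot), 0, params$pixel_sd))
    # SP-B analog channel: background only (quantification targets SP-C)
    spb <- 10^rnorm(n, params$background_mu, params$background_sigma)
    # melittin marker channel
    mel <- 10^rnorm(n, params$background_mu, params$background_sigma)
    mel[on_spot] <- 10^(params$background_mu + params$melittin_log10 +
                          rnorm(sum(on_spot), 0, params$melittin_sigma))

    raw <- cbind(mel, spc, spb) * 10^batch
    pk <- assemble_pixels(c(MZ_MELITTIN, MZ_SPC, MZ_SPB), raw)
    ds <- msi_dataset(data.frame(x = px, y = py), pk$mz, pk$intensity,
                      grid_shape = params$grid_shape,
                      sample_id = sprintf("calib_e%d_r%d", experiment, replicate),
                      group = "calibration")
    attr(ds, "truth") <- list(
      spot_masks = spot_masks, amounts = params$amounts,
      c_pixel = c_pixel, centers = centers,
      experiment = experiment, replicate = replicate,
      exp_effect = exp_eff, batch_offset = batch, params = params)
    ds
  })
}

#' Generate the full set of calibration slides for a design
#'
#' @param params a [calib_sim_params()].
#' @return A list of [msi_dataset()] slides (experiments x replicates).
#' @export
generate_calibration_slides <- function(params) {
  out <- list()
  for (e in seq_len(params$n_experiments)) {
    for (r in seq_len(params$n_replicates)) {
      out[[length(out) + 1L]] <- generate_calibration_slide(params, e, r)
    }
  }
  out
}

#' Parameters for a synthetic animal cohort
#'
#' Defaults follow the study design: 7 surfactant-treated and 5 control
#' preterm lambs, physiological sampling at 0, 5, 30, 60, 90 and 120
#' minutes.  Each treated animal draws a latent peripheral-deposition
#' factor (lognormal) that scales both the peptide abundance of its lung
#' section and the physiological improvement: PaO2 and Cdyn shift upward,
#' PIP downward, PaCO2 downward.  Controls get abundance 0 and no
#' improvement.  PaO2/PaCO2 noise is Gaussian on the log10 scale; other
#' parameters carry Gaussian noise on the linear scale.
#'
#' @param n_treated,n_control animal counts (each >= 2).
#' @param timepoints sampling times in minutes, strictly increasing.
#' @param deposition_meanlog,deposition_sdlog lognormal parameters of the
#'   latent deposition factor.
#' @param effect_map named list of full-effect sizes at deposition 1:
#'   `PaO2` and `PaCO2` on the log10 scale, `Cdyn` (mL/kg/cmH2O), `PIP`
#'   (cmH2O), `VT` (mL/kg), `MAP` (cmH2O), `pH`, `BE` (mmol/L).
#' @param noise_sd named list of per-parameter noise SDs (log10 scale for
#'   PaO2/PaCO2, parameter units otherwise).
#' @param onset_min minutes over which the treatment effect ramps to full.
#' @param batch_sd SD of the per-animal section batch offset (log10).
#' @param seed integer seed.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_treated = 7L, n_control = 5L,
                              timepoints = c(0, 5, 30, 60, 90, 120),
                              deposition_meanlog = 0,
                              deposition_sdlog = 0.4,
                              effect_map = list(PaO2 = 0.45, PaCO2 = -0.25,
                                                Cdyn = 0.12, PIP = -6,
                                                VT = 1.5, MAP = -3,
                                                pH = 0.12, BE = 4),
                              noise_sd = list(PaO2 = 0.05, PaCO2 = 0.04,
                                              pH = 0.03, BE = 1.5,
                                              Cdyn = 0.02, PIP = 1.0,
                                              VT = 0.5, MAP = 1.0, HR = 8),
                              onset_min = 30,
                              batch_sd = 0.2,
                              seed = 1L) {
  if (n_treated < 2L || n_control < 2L) {
    stop("need at least 2 animals per group")
  }
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  structure(
    list(n_treated = as.integer(n_treated), n_control = as.integer(n_control),
         timepoints = timepoints,
         deposition_meanlog = deposition_meanlog,
         deposition_sdlog = deposition_sdlog,
         effect_map = effect_map, noise_sd = noise_sd,
         onset_min = onset_min, batch_sd = batch_sd,
         seed = as.integer(seed)),
    class = "cohort_sim_params")
}

# baselines after 15 min of mechanical ventilation (immature lung)
cohort_baselines <- list(
  PaO2 = 55,    # mmHg (modelled on the log10 scale)
  PaCO2 = 115,  # mmHg (log10 scale)
  pH = 7.05,
  BE = -12,     # mmol/L
  Cdyn = 0.13,  # mL/kg/cmH2O
  PIP = 34,     # cmH2O
  VT = 5.5,     # mL/kg
  MAP = 16,     # cmH2O
  HR = 160)     # bpm

#' Generate a synthetic animal cohort
#'
#' @param params a [cohort_sim_params()].
#' @return A list with `physio` (long tibble: animal_id, group, time_min,
#'   parameter, value), `section_params` (named list of
#'   [section_sim_params()], one per animal), and `truth` (tibble of latent
#'   deposition factors).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_preserved_seed(params$seed, {
    ids <- c(sprintf("SF%02d", seq_len(params$n_treated)),
             sprintf("C%02d", seq_len(params$n_control)))
    groups <- rep(c("treated", "control"),
                  c(params$n_treated, params$n_control))
    depo <- ifelse(groups == "treated",
                   stats::rlnorm(length(ids), params$deposition_meanlog,
                                 params$deposition_sdlog), 0)
    tp <- params$timepoints
    ramp <- pmin(pmax(tp / params$onset_min, 0), 1)
    ramp[tp == 0] <- 0   # baseline sample precedes treatment

    log_scale <- c("PaO2", "PaCO2")
    n_a <- length(ids); n_t <- length(tp)
    rows_out <- lapply(names(cohort_baselines), function(p) {
      base <- cohort_baselines[[p]]
      eff <- params$effect_map[[p]] %||% 0
      sd_p <- params$noise_sd[[p]] %||% 0
      # animal-major layout: mu[a, t] = baseline + effect * deposition * ramp
      mu <- outer(depo, ramp, function(d, r) eff * d * r)
      noise <- matrix(rnorm(n_a * n_t, 0, sd_p), n_a, n_t)
      val <- if (p %in% log_scale) {
        10^(log10(base) + mu + noise)
      } else {
        base + mu + noise
      }
      tibble::tibble(
        animal_id = rep(ids, each = n_t),
        group = rep(groups, each = n_t),
        time_min = rep(tp, n_a),
        parameter = p,
        value = as.vector(t(val)))
    })
    physio <- dplyr::bind_rows(rows_out) |>
      dplyr::arrange(match(.data$animal_id, ids))

    section_params <- stats::setNames(lapply(seq_along(ids), function(a) {
      section_sim_params(
        abundance_scale = depo[a],
        batch_offset = rnorm(1, 0, params$batch_sd),
        seed = params$seed + 293L * a,
        sample_id = ids[a],
        group = groups[a])
    }), ids)

    list(physio = physio,
         section_params = section_params,
         truth = tibble::tibble(animal_id = ids, group = groups,
                                deposition = depo))
  })
}

#' Load simulation parameters from a YAML file
#'
#' The file must carry a top-level `kind` field (`section`, `calibration`
#' or `cohort`); remaining fields are passed to the matching constructor.
#' The packaged default calibration design is at
#' `system.file("extdata", "calibration_default.yaml", package = "surfmsi")`.
#'
#' @param path YAML file path.
#' @return A parameter object of the matching class.
#' @export
sim_params_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  kind <- y$kind %||% stop("YAML parameter file needs a 'kind' field")
  y$kind <- NULL
  ctor <- switch(kind,
                 section = section_sim_params,
                 calibration = calib_sim_params,
                 cohort = cohort_sim_params,
                 stop("unknown parameter kind: ", kind))
  do.call(ctor, y)
}

#' Write the ground-truth sidecar of a synthetic dataset as JSON
#'
#' @param dataset a generated [msi_dataset()] carrying a `truth` attribute.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(dataset, path) {
  tr <- attr(dataset, "truth")
  if (is.null(tr)) stop("dataset carries no ground-truth attribute")
  out <- list(sample_id = dataset$sample_id, group = dataset$group)
  if (!is.null(tr$tissue)) out$tissue <- which(tr$tissue) - 1L
  if (!is.null(tr$spot_masks)) {
    out$spot_pixels <- lapply(tr$spot_masks, function(m) which(m) - 1L)
    out$amounts <- tr$amounts
    out$c_pixel <- tr$c_pixel
  }
  if (!is.null(tr$params$abundance_scale)) {
    out$abundance_scale <- tr$params$abundance_scale
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
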