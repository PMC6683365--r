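# Simulation studies over many seeds: calibration parameter recovery,
# association sign recovery across synthetic cohorts, and null-cohort
# type-I calibration of the group comparison.  These are the workhorses of
# the analysis drivers and of the acceptance checks.

#' Calibration parameter-recovery study
#'
#' Repeats the full calibration pipeline (slide simulation under the
#' packaged default design, background clustering and subtraction, melittin
#' spot detection, per-spot `c_pixel` and mean signal, mixed-effects fit)
#' across seeds, recording the fitted fixed effects, their 95% CIs and
#' whether the CIs cover the generating values.
#'
#' @param n_seeds number of independent simulated calibration studies.
#' @param base_seed seeds used are `base_seed + 1 ... base_seed + n_seeds`.
#' @param params_yaml path of the YAML calibration design; default the
#'   packaged design (3 experiments x 2 replicates, 1-50 ng, slope 3.1,
#'   intercept 0.2).
#' @return A tibble with one row per seed: `seed`, `slope`, `intercept`,
#'   CI bounds, `covers_slope`, `covers_intercept`, `method`; the
#'   generating values are attached as attribute `generating`.
#' @export
calibration_recovery_study <- function(n_seeds = 50L, base_seed = 1000L,
                                       params_yaml = system.file(
                                         "extdata", "calibration_default.yaml",
                                         package = "surfmsi")) {
  base <- sim_params_from_yaml(params_yaml)
  rows <- lapply(seq_len(n_seeds), function(i) {
    p <- base
    p$seed <- as.integer((base_seed + i) %% .Machine$integer.max)
    slides <- generate_calibration_slides(p)
    f <- suppressWarnings(run_calibration(slides, p$amounts)$fit)
    tibble::tibble(
      seed = p$seed,
      slope = f$slope, slope_lo = f$slope_ci[1], slope_hi = f$slope_ci[2],
      intercept = f$intercept,
      intercept_lo = f$intercept_ci[1], intercept_hi = f$intercept_ci[2],
      covers_slope = f$slope_ci[1] <= base$slope & base$slope <= f$slope_ci[2],
      covers_intercept = f$intercept_ci[1] <= base$intercept &
        base$intercept <= f$intercept_ci[2],
      method = f$method)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "generating") <- list(slope = base$slope, intercept = base$intercept)
  out
}

# low-noise cohort design used by the sign-recovery study
low_noise_cohort <- function(seed) {
  cohort_sim_params(
    seed = seed,
    noise_sd = list(PaO2 = 0.02, PaCO2 = 0.02, pH = 0.01, BE = 0.5,
                    Cdyn = 0.01, PIP = 0.5, VT = 0.2, MAP = 0.5, HR = 4))
}

#' Association sign-recovery study
#'
#' For each seed, simulates a 7-treated / 5-control cohort whose latent
#' deposition factor drives both the lung-section peptide abundance and the
#' physiological response, runs the full MSI chain (section simulation,
#' ion extraction, log transform, segmentation, mode subtraction,
#' control-pooled noise threshold, section summaries) on the SP-B analog
#' channel, and records the signs of the Spearman correlations of
#' PaO2/Cdyn/PIP AUC with the section sum summary.
#'
#' @param n_seeds number of simulated cohorts.
#' @param base_seed first seed minus one.
#' @param grid_shape section grid used for the per-animal images (kept
#'   small; the summaries only need enough pixels for stable ranks).
#' @return A tibble with per-seed Spearman rho for the three parameters
#'   against `sum_log10_I` of the SP-B analog, and `sign_ok` (positive for
#'   PaO2 and Cdyn, negative for PIP).
#' @export
association_sign_study <- function(n_seeds = 100L, base_seed = 2000L,
                                   grid_shape = c(20L, 20L)) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    co <- generate_cohort(low_noise_cohort(
      as.integer((base_seed + i) %% .Machine$integer.max)))
    sp <- lapply(co$section_params, function(p) {
      p$grid_shape <- as.integer(grid_shape)
      p
    })
    sections <- lapply(sp, generate_section)
    pr <- process_sections(sections, ions = c("SP-B analog" = 3886))
    sm <- summarize_physio(transform_physio(co$physio))
    res <- associate(sm, pr$summaries)
    rho_of <- function(param) {
      res$rho[res$parameter == param & res$metric == "sum_log10_I"]
    }
    tibble::tibble(
      seed = base_seed + i,
      rho_pao2 = rho_of("PaO2_AUC"),
      rho_cdyn = rho_of("Cdyn_AUC"),
      rho_pip = rho_of("PIP_AUC"),
      sign_ok = rho_of("PaO2_AUC") > 0 & rho_of("Cdyn_AUC") > 0 &
        rho_of("PIP_AUC") < 0)
  })
  dplyr::bind_rows(rows)
}

#' Null-cohort type-I calibration of the group comparison
#'
#' Simulates cohorts with a zero effect map (treatment does nothing) and
#' records how often the PaO2 AUC group comparison rejects at alpha.
#'
#' @param n_cohorts number of null cohorts.
#' @param base_seed first seed minus one.
#' @param alpha nominal level.
#' @return A list with `rejection_rate` and the per-cohort p-values.
#' @export
null_rejection_study <- function(n_cohorts = 500L, base_seed = 3000L,
                                 alpha = 0.05) {
  null_effects <- list(PaO2 = 0, PaCO2 = 0, Cdyn = 0, PIP = 0,
                       VT = 0, MAP = 0, pH = 0, BE = 0)
  pvals <- vapply(seq_len(n_cohorts), function(i) {
    co <- generate_cohort(cohort_sim_params(
      seed = as.integer((base_seed + i) %% .Machine$integer.max),
      effect_map = null_effects))
    ph <- co$physio[co$physio$parameter == "PaO2", ]
    ph$value <- log10(ph$value)
    auc <- vapply(split(ph, ph$animal_id), function(s) {
      s <- s[order(s$time_min), ]
      compute_auc(s$time_min, s$value)
    }, numeric(1))
    grp <- co$truth$group[match(names(auc), co$truth$animal_id)]
    group_compare(auc[grp == "treated"], auc[grp == "control"])$p
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), p_values = pvals)
}
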