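# Per-animal physiological time courses.  Input is a long table
# (animal_id, group, time_min, parameter, value).  PaO2 and PaCO2 are
# log10-transformed before analysis; each series is summarized by its
# trapezoidal AUC and the value at the final time point (120 min); groups
# are compared by Student's t-test routed through Levene's test for
# equality of variances; MSI section summaries are associated with the
# physiological summaries by Spearman correlation over treated animals.

PHYSIO_LOG_PARAMS <- c("PaO2", "PaCO2")

#' Dynamic lung compliance
#'
#' `Cdyn = delta_V / (delta_P * weight)`: the tidal volume change divided
#' by the driving pressure, standardized by body weight.
#'
#' @param delta_v lung volume change (tidal volume) in mL.
#' @param delta_p pressure change (PIP - PEEP) in cmH2O, > 0.
#' @param weight body weight in kg, > 0.
#' @return Cdyn in mL/kg/cmH2O.
#' @export
compute_cdyn <- function(delta_v, delta_p, weight) {
  if (any(delta_p <= 0)) stop("delta_p must be positive")
  if (any(weight <= 0)) stop("weight must be positive")
  delta_v / (delta_p * weight)
}

#' Log10-transform the blood-gas parameters of a physiology table
#'
#' Replaces PaO2 and PaCO2 values by their log10 (they are distinctly
#' non-normal on the raw scale); all other parameters pass through
#' unchanged.  The returned table carries a transform flag and the
#' function refuses re-application.
#'
#' @param physio long tibble (`animal_id`, `group`, `time_min`,
#'   `parameter`, `value`).
#' @return The transformed tibble with attribute `log10_applied = TRUE`.
#' @export
transform_physio <- function(physio) {
  if (isTRUE(attr(physio, "log10_applied"))) {
    stop("physiology table is already log10-transformed; refusing to ",
         "transform twice")
  }
  sel <- physio$parameter %in% PHYSIO_LOG_PARAMS
  bad <- sel & physio$value <= 0
  if (any(bad)) {
    b <- physio[which(bad)[1L], ]
    stop(sprintf(
      "non-positive %s value for animal %s at %g min: cannot log-transform",
      b$parameter, b$animal_id, b$time_min))
  }
  physio$value[sel] <- log10(physio$value[sel])
  attr(physio, "log10_applied") <- TRUE
  physio
}

#' Trapezoidal area under a time course
#'
#' @param time_min sampling times in minutes, strictly increasing (>= 2).
#' @param values parameter values at those times.
#' @return AUC in parameter-units x minutes on the analysis scale.
#' @export
compute_auc <- function(time_min, values) {
  if (length(time_min) < 2L) stop("need at least 2 timepoints for an AUC")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (length(values) != length(time_min)) stop("times and values differ in length")
  sum(diff(time_min) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Value of a series at a fixed time point
#'
#' @param time_min,values the series.
#' @param t the requested time (default 120 min); must be present exactly,
#'   no interpolation.
#' @return The value at `t`.
#' @export
endpoint <- function(time_min, values, t = 120) {
  i <- which(time_min == t)
  if (length(i) != 1L) {
    stop("time point ", t, " min not present in the series (observed: ",
         paste(time_min, collapse = ", "), ")")
  }
  values[i]
}

#' Summarize every animal x parameter series
#'
#' @param physio long physiology tibble, already passed through
#'   [transform_physio()] (a warning is raised otherwise).
#' @param endpoint_time final time point in minutes (default 120).
#' @return Tibble with `animal_id`, `group`, `parameter`, `auc`,
#'   `endpoint`.
#' @export
summarize_physio <- function(physio, endpoint_time = 120) {
  if (!isTRUE(attr(physio, "log10_applied"))) {
    warning("physiology table not log10-transformed; summarizing raw values")
  }
  physio |>
    dplyr::group_by(.data$animal_id, .data$group, .data$parameter) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      auc = compute_auc(.data$time_min, .data$value),
      endpoint = endpoint(.data$time_min, .data$value, endpoint_time),
      .groups = "drop")
}

#' Compare one summary between treated and control animals
#'
#' Levene's test (Brown-Forsythe, median-centred) decides between the
#' pooled-variance and the Welch t-test at alpha = 0.05; the two-sided t
#' statistic and p-value are reported.
#'
#' @param treated,control numeric summary vectors (>= 2 each).
#' @return A list of class `group_test`: `t`, `p`, `levene_p`,
#'   `variance_assumption` (`"equal"` or `"unequal"`), `n_treated`,
#'   `n_control`.
#' @export
group_compare <- function(treated, control) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  if (length(treated) < 2L || length(control) < 2L) {
    stop("need at least 2 animals per group")
  }
  if (stats::var(treated) == 0 && stats::var(control) == 0) {
    stop("zero variance in both groups: t-test undefined")
  }
  g <- factor(rep(c("treated", "control"),
                  c(length(treated), length(control))))
  lev <- car::leveneTest(c(treated, control) ~ g, center = stats::median)
  lev_p <- lev[["Pr(>F)"]][1L]
  equal <- is.na(lev_p) || lev_p >= 0.05
  tt <- stats::t.test(treated, control, var.equal = equal)
  structure(
    list(t = unname(tt$statistic), p = tt$p.value, levene_p = lev_p,
         variance_assumption = if (equal) "equal" else "unequal",
         n_treated = length(treated), n_control = length(control)),
    class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "<group_test> t = %.3f, p = %.4g (%s variances; Levene p = %.3g; n = %d vs %d)\n",
    x$t, x$p, x$variance_assumption, x$levene_p, x$n_treated, x$n_control))
  invisible(x)
}

#' Group comparison for every parameter and summary
#'
#' @param summaries output of [summarize_physio()].
#' @return Tibble with one row per parameter x summary (`auc`,
#'   `endpoint`): `t`, `p`, `levene_p`, `variance_assumption`.
#' @export
group_compare_all <- function(summaries) {
  rows <- list()
  for (p in unique(summaries$parameter)) {
    sub <- summaries[summaries$parameter == p, ]
    for (stat in c("auc", "endpoint")) {
      gt <- group_compare(sub[[stat]][sub$group == "treated"],
                          sub[[stat]][sub$group == "control"])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = p, summary = stat, t = gt$t, p_value = gt$p,
        levene_p = gt$levene_p,
        variance_assumption = gt$variance_assumption)
    }
  }
  dplyr::bind_rows(rows)
}

#' Associate physiological summaries with MSI section summaries
#'
#' Spearman rank correlation, over treated animals, of each physiological
#' AUC summary (by default PaO2, Cdyn and PIP) against each MSI metric
#' (`avg_log10_I`, `sum_log10_I`) of each ion.  Ties take average ranks.
#'
#' @param physio_summaries output of [summarize_physio()].
#' @param msi_summaries row-bound [section_summary()] tibbles with
#'   `sample_id` matching `animal_id`.
#' @param parameters physiological parameters to associate (AUC is used).
#' @param adjust apply Benjamini-Hochberg correction to the p-values
#'   (default FALSE, mirroring an exploratory association screen).
#' @return Tibble with `parameter`, `metric`, `ion`, `rho`, `p_value`, `n`.
#' @export
associate <- function(physio_summaries, msi_summaries,
                      parameters = c("PaO2", "Cdyn", "PIP"),
                      adjust = FALSE) {
  phys <- physio_summaries[physio_summaries$group == "treated" &
                             physio_summaries$parameter %in% parameters, ]
  rows <- list()
  for (p in parameters) {
    pa <- phys[phys$parameter == p, c("animal_id", "auc")]
    for (ion_label in unique(msi_summaries$ion)) {
      mi <- msi_summaries[msi_summaries$ion == ion_label, ]
      merged <- merge(pa, mi, by.x = "animal_id", by.y = "sample_id")
      if (nrow(merged) < 3L) {
        stop("fewer than 3 treated animals with both physiology and MSI ",
             "summaries for ", p, " x ", ion_label)
      }
      for (metric in c("avg_log10_I", "sum_log10_I")) {
        ct <- suppressWarnings(
          stats::cor.test(merged$auc, merged[[metric]], method = "spearman"))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          parameter = paste0(p, "_AUC"), metric = metric, ion = ion_label,
          rho = unname(ct$estimate), p_value = ct$p.value,
          n = nrow(merged))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Read / write the long physiology table as TSV
#'
#' Columns: `animal_id`, `group`, `time_min`, `parameter`, `value`.
#'
#' @param physio tibble to write.
#' @param path TSV path.
#' @return `read_physio_tsv` returns the tibble; the writer returns `path`
#'   invisibly.
#' @export
write_physio_tsv <- function(physio, path) {
  readr::write_tsv(physio, path)
  invisible(path)
}

#' @rdname write_physio_tsv
#' @export
read_physio_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    group = readr::col_character(),
    time_min = readr::col_double(),
    parameter = readr::col_character(),
    value = readr::col_double()))
}
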