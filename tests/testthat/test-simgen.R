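test_that("identical parameters and seed give identical sections", {
  p <- section_sim_params(grid_shape = c(12L, 14L), seed = 5)
  d1 <- generate_section(p)
  d2 <- generate_section(p)
  expect_identical(unclass(d1), unclass(d2))
  d3 <- generate_section(section_sim_params(grid_shape = c(12L, 14L), seed = 6))
  expect_false(identical(d1$intensity, d3$intensity))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_section(section_sim_params(grid_shape = c(6L, 6L), seed = 1)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("control sections carry background only in the peptide channels", {
  p <- section_sim_params(abundance_scale = 0, batch_offset = 0.4,
                          grid_shape = c(40L, 40L), seed = 8)
  d <- generate_section(p)
  expect_equal(d$group, "control")
  lg <- log10(extract_ion_image(d, 3618, 1)$values)
  # the log10 intensity mode sits at background_mu + batch_offset
  md <- estimate_mode(as.vector(lg))
  grid_step <- diff(range(lg)) / 511
  expect_lt(abs(md - (p$background_mu + p$batch_offset)), max(grid_step, 0.02) + 0.03)
  # and the distribution is background-like everywhere: no heavy upper tail
  expect_lt(mean(lg > p$background_mu + p$batch_offset + 4 * p$background_sigma),
            0.005)
})

test_that("the SP-C:SP-B intensity ratio of the formulation is respected", {
  d <- generate_section(section_sim_params(sp_ratio = 7.5, seed = 3,
                                           grid_shape = c(30L, 30L)))
  tis <- attr(d, "truth")$tissue
  spc <- extract_ion_image(d, 3618, 1)$values
  spb <- extract_ion_image(d, 3886, 1)$values
  expect_gt(mean(spc[tis]), mean(spb[tis]))
  # ratio of mean signals is near the configured 7.5
  expect_equal(mean(spc[tis]) / mean(spb[tis]), 7.5, tolerance = 0.35)
})

test_that("invalid section parameters are rejected", {
  expect_error(section_sim_params(tissue_phantom = list(semiaxes = c(1.4, 0.5))),
               "larger than the grid")
  expect_error(section_sim_params(background_sigma = 0), "background_sigma")
  expect_error(section_sim_params(sp_ratio = -1), "sp_ratio")
  expect_error(section_sim_params(grid_shape = c(0L, 5L)), "grid_shape")
})

test_that("a noise-free calibration slide stamps the exact calibration law", {
  p <- noise_free_calib()
  sl <- generate_calibration_slide(p, 1, 1)
  tr <- attr(sl, "truth")
  img <- extract_ion_image(sl, 3618, 1)
  for (s in seq_along(p$amounts)) {
    m <- tr$spot_masks[[s]]
    expect_equal(log10(img$values[m]),
                 rep(p$slope * tr$c_pixel[s] + p$intercept, sum(m)),
                 tolerance = 1e-9)
  }
  # OLS on the true spot means recovers the generating law to floating point
  means <- vapply(seq_along(p$amounts),
                  function(s) mean(log10(img$values[tr$spot_masks[[s]]])),
                  numeric(1))
  fit <- lm(means ~ tr$c_pixel)
  expect_equal(unname(coef(fit)), c(p$intercept, p$slope), tolerance = 1e-9)
})

test_that("replicate slides share their experiment effect; slides are deterministic", {
  p <- calib_sim_params(seed = 4)
  r1 <- attr(generate_calibration_slide(p, 2, 1), "truth")
  r2 <- attr(generate_calibration_slide(p, 2, 2), "truth")
  e1 <- attr(generate_calibration_slide(p, 1, 1), "truth")
  expect_identical(r1$exp_effect, r2$exp_effect)
  expect_false(identical(r1$exp_effect, e1$exp_effect))
  again <- generate_calibration_slide(p, 2, 1)
  expect_identical(unclass(generate_calibration_slide(p, 2, 1)), unclass(again))
})

test_that("calibration design yields six spots per slide and rejects overlap", {
  p <- calib_sim_params(seed = 1)
  sl <- generate_calibration_slide(p, 1, 1)
  expect_length(attr(sl, "truth")$spot_masks, 6L)
  expect_error(generate_calibration_slide(
    calib_sim_params(spot_radius = 12, seed = 1), 1, 1), "overlap")
  expect_error(calib_sim_params(amounts = c(5, 2, 1)), "increasing")
  expect_error(calib_sim_params(slope = 0), "slope")
})

test_that("melittin spot detection recovers the stamped pixel sets", {
  p <- calib_sim_params(seed = 12)
  sl <- generate_calibration_slide(p, 1, 1)
  tr <- attr(sl, "truth")
  mel <- extract_ion_image(sl, 2846, 1)
  spots <- detect_spots(mel, expected_n = 6L)
  # match detected components to stamped masks by best overlap
  for (truth_mask in tr$spot_masks) {
    jac <- vapply(spots, function(m) {
      sum(m & truth_mask) / sum(m | truth_mask)
    }, numeric(1))
    expect_gte(max(jac), 0.9)
  }
})

test_that("cohort defaults follow the study design and link deposition to outcome", {
  p <- cohort_sim_params(seed = 2)
  co <- generate_cohort(p)
  expect_equal(sum(co$truth$group == "treated"), 7L)
  expect_equal(sum(co$truth$group == "control"), 5L)
  expect_true(all(co$truth$deposition[co$truth$group == "control"] == 0))
  expect_setequal(unique(co$physio$time_min), c(0, 5, 30, 60, 90, 120))
  # matched section parameters inherit the latent deposition factor
  ab <- vapply(co$section_params, `[[`, numeric(1), "abundance_scale")
  expect_equal(unname(ab), co$truth$deposition)
})

test_that("with zero noise the PaO2 AUC rank order equals the deposition rank order", {
  p <- cohort_sim_params(
    seed = 31,
    noise_sd = list(PaO2 = 0, PaCO2 = 0, pH = 0, BE = 0, Cdyn = 0,
                    PIP = 0, VT = 0, MAP = 0, HR = 0))
  co <- generate_cohort(p)
  sm <- summarize_physio(transform_physio(co$physio))
  pa <- sm[sm$parameter == "PaO2" & sm$group == "treated", ]
  pa <- pa[match(co$truth$animal_id[co$truth$group == "treated"],
                 pa$animal_id), ]
  expect_identical(order(pa$auc),
                   order(co$truth$deposition[co$truth$group == "treated"]))
})

test_that("a null effect map makes treated and control series exchangeable", {
  p <- cohort_sim_params(
    seed = 17,
    effect_map = list(PaO2 = 0, PaCO2 = 0, Cdyn = 0, PIP = 0,
                      VT = 0, MAP = 0, pH = 0, BE = 0))
  co <- generate_cohort(p)
  pa <- co$physio[co$physio$parameter == "PaO2", ]
  # identical generating distribution: a t-test on log10 values at 120 min
  v <- log10(pa$value[pa$time_min == 120])
  g <- pa$group[pa$time_min == 120]
  expect_gt(t.test(v[g == "treated"], v[g == "control"])$p.value, 0.01)
})

test_that("YAML parameter files round-trip through the constructors", {
  path <- system.file("extdata", "calibration_default.yaml", package = "surfmsi")
  expect_true(nzchar(path))
  p <- sim_params_from_yaml(path)
  expect_s3_class(p, "calib_sim_params")
  expect_equal(p$amounts, c(1, 2.5, 5, 10, 25, 50))
  expect_equal(p$melittin_amount, 6.25)
  expect_equal(p$slope, 3.1)
  expect_equal(p$intercept, 0.2)
  expect_equal(p$n_experiments, 3L)
  tdir <- withr::local_tempdir()
  sec <- file.path(tdir, "sec.yaml")
  writeLines(c("kind: section", "seed: 3", "abundance_scale: 0.5"), sec)
  ps <- sim_params_from_yaml(sec)
  expect_s3_class(ps, "section_sim_params")
  expect_equal(ps$abundance_scale, 0.5)
  bad <- file.path(tdir, "bad.yaml")
  writeLines("kind: nonsense", bad)
  expect_error(sim_params_from_yaml(bad), "unknown parameter kind")
})

test_that("ground-truth sidecars serialize to JSON", {
  d <- generate_section(section_sim_params(grid_shape = c(6L, 6L), seed = 2))
  tdir <- withr::local_tempdir()
  f <- write_truth_json(d, file.path(tdir, "truth.json"))
  j <- jsonlite::read_json(f)
  expect_equal(j$sample_id, d$sample_id)
  expect_length(j$tissue, sum(attr(d, "truth")$tissue))
})
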