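test_that("log transform applies the pseudocount and preserves ranking", {
  img <- ion_image(matrix(c(0, 99, 9, NA), 2, 2), 3618, 1)
  lg <- log_transform(img, pseudocount = 1)
  expect_equal(lg$values[1, 1], 0)           # log10(0 + 1)
  expect_equal(lg$values[2, 1], 2)           # log10(99 + 1)
  expect_equal(lg$values[1, 2], 1)
  expect_true(is.na(lg$values[2, 2]))        # missing stays missing
  v <- matrix(surfmsi:::with_preserved_seed(1, runif(25, 0, 1e4)), 5, 5)
  expect_identical(order(log_transform(ion_image(v, 3618, 1), 1)$values),
                   order(v))
  expect_error(log_transform(img, 0), "pseudocount")
})

test_that("two-population clustering recovers well-separated components", {
  x <- surfmsi:::with_preserved_seed(7, {
    c(rnorm(600, 0.1, 0.08), rnorm(250, 1.5, 0.2))
  })
  lg <- wrap_log_image(matrix(x, 25, 34))
  cl <- classify_background(lg)
  expect_equal(unname(cl$means["background"]), 0.1, tolerance = 0.05)
  expect_equal(unname(cl$means["signal"]), 1.5, tolerance = 0.1)
  expect_equal(sum(cl$background), 600, tolerance = 0.02)
})

test_that("cluster labels are invariant under a constant shift", {
  x <- surfmsi:::with_preserved_seed(8, c(rnorm(300, 0, 0.1), rnorm(100, 2, 0.3)))
  lg1 <- wrap_log_image(matrix(x, 20, 20))
  lg2 <- wrap_log_image(matrix(x + 0.73, 20, 20))
  cl1 <- classify_background(lg1)
  cl2 <- classify_background(lg2)
  expect_identical(cl1$background, cl2$background)
  expect_equal(unname(cl2$means - cl1$means), c(0.73, 0.73), tolerance = 1e-8)
})

test_that("constant intensities fall back to a single background cluster", {
  lg <- wrap_log_image(matrix(2.5, 4, 4))
  expect_warning(cl <- classify_background(lg), "single-cluster")
  expect_true(all(cl$background))
  expect_true(is.na(cl$means["signal"]))
  expect_error(classify_background(wrap_log_image(matrix(1, 1, 1))),
               "at least 2")
})

test_that("the density mode estimator finds the dominant component", {
  # symmetric sample: mode approximates the mean
  x <- surfmsi:::with_preserved_seed(11, rnorm(10000, 1.3, 0.4))
  expect_equal(estimate_mode(x), 1.3, tolerance = 0.05)
  # point mass
  expect_equal(estimate_mode(rep(4.2, 50)), 4.2)
  # bimodal with dominant low component returns the low mode
  y <- surfmsi:::with_preserved_seed(12, c(rnorm(5000, 0, 0.15), rnorm(900, 2, 0.15)))
  expect_equal(estimate_mode(y), 0, tolerance = 0.05)
  expect_error(estimate_mode(1:9), "at least 10")
})

test_that("batch correction zeroes the background mode across samples", {
  for (off in c(0.3, 0.9)) {
    p <- section_sim_params(abundance_scale = 0, batch_offset = off,
                            grid_shape = c(40L, 40L), seed = 20 + off * 10)
    d <- generate_section(p)
    pre <- preprocess_ion(d, 3618, tissue = matrix(TRUE, 40, 40))
    v <- pre$corrected$values
    md <- estimate_mode(as.vector(v))
    grid_step <- diff(range(v, na.rm = TRUE)) / 511
    expect_lt(abs(md), grid_step + 1e-9)
    # idempotence: a second mode estimate on corrected data is ~0
    m2 <- background_model(pre$corrected, mask = matrix(TRUE, 40, 40))
    expect_lt(abs(m2$background_mode), 2 * grid_step + 1e-9)
  }
})

test_that("batch correction is a monotone per-sample shift", {
  lg <- wrap_log_image(matrix(surfmsi:::with_preserved_seed(5, rnorm(400, 1, 0.3)), 20, 20))
  mdl <- background_model(lg)
  corr <- batch_correct(lg, mdl)
  expect_equal(corr$values, lg$values - mdl$background_mode)
  expect_identical(order(corr$values), order(lg$values))
})

test_that("the noise threshold is the configured empirical quantile", {
  x <- surfmsi:::with_preserved_seed(30, rnorm(1e5))
  thr <- estimate_noise_threshold(x, 0.995)
  expect_equal(thr, qnorm(0.995), tolerance = 0.05)  # 2.576 within MC error
  frac <- mean(x > thr)
  expect_gte(frac, 0.003); expect_lte(frac, 0.007)
  expect_equal(estimate_noise_threshold(rep(1.5, 100)), 1.5)
  expect_error(estimate_noise_threshold(numeric(0)), "empty")
  expect_error(estimate_noise_threshold(x, 1.2), "quantile")
})

test_that("above-noise masking is strict and confined to tissue", {
  v <- matrix(c(0.1, 0.2, 0.5, 0.9), 2, 2)
  lg <- wrap_log_image(v)
  tis <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  m <- above_noise_mask(lg, 0.2, tis)
  expect_identical(m, matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))  # ties below
  expect_identical(above_noise_mask(lg, Inf * -1, tis), tis)
  expect_false(any(above_noise_mask(lg, 10, tis)))
})

test_that("high-SNR treated sections have most true-signal pixels above noise", {
  ctrl <- generate_section(section_sim_params(abundance_scale = 0, seed = 40,
                                              grid_shape = c(40L, 40L)))
  trt <- generate_section(section_sim_params(abundance_scale = 30, seed = 41,
                                             grid_shape = c(40L, 40L)))
  pr <- process_sections(list(trt, ctrl), ions = c("SP-C analog" = 3618))
  s <- pr$samples[[trt$sample_id]]
  truth <- attr(trt, "truth")$signal
  hit <- sum(s$ions[["SP-C analog"]]$masks$above_noise & truth) / sum(truth)
  expect_gte(hit, 0.9)
})

test_that("tissue segmentation recovers the elliptical phantom", {
  d <- generate_section(section_sim_params(grid_shape = c(40L, 40L), seed = 50))
  mask <- segment_tissue(d)
  truth <- attr(d, "truth")$tissue
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jac, 0.95)
  # a homogenate-coated calibration slide segments as the full grid
  sl <- generate_calibration_slide(calib_sim_params(seed = 5), 1, 1)
  expect_equal(mean(segment_tissue(sl)), 1, tolerance = 0.02)
})

test_that("pixel-mask invariants are enforced", {
  t2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  an <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  bg <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  m <- pixel_masks(t2, an, bg)
  expect_s3_class(m, "pixel_masks")
  expect_error(pixel_masks(t2, matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2), bg),
               "inside the tissue")
  expect_error(pixel_masks(t2, an, an), "both background and above-noise")
})

test_that("independent background models per ion channel", {
  d <- generate_section(section_sim_params(seed = 60, grid_shape = c(30L, 30L)))
  ctrl <- generate_section(section_sim_params(abundance_scale = 0, seed = 61,
                                              grid_shape = c(30L, 30L)))
  pr <- process_sections(list(d, ctrl))
  ms <- pr$samples[[d$sample_id]]$ions
  expect_named(ms, c("SP-C analog", "SP-B analog"))
  expect_false(isTRUE(all.equal(ms[["SP-C analog"]]$model$background_mode,
                                ms[["SP-B analog"]]$model$background_mode)))
})
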