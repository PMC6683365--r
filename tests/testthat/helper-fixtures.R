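# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no stored data.

# tiny dataset with random sparse peak lists on a rows x cols grid
random_peak_dataset <- function(seed, rows = 4L, cols = 5L,
                                max_peaks = 8L, drop_pixels = 0L) {
  surfmsi:::with_preserved_seed(seed, {
    coords <- expand.grid(x = 0:(cols - 1L), y = 0:(rows - 1L))
    if (drop_pixels > 0L) {
      coords <- coords[-sample(nrow(coords), drop_pixels), , drop = FALSE]
    }
    n <- nrow(coords)
    mz <- lapply(seq_len(n), function(i) {
      k <- sample(0:max_peaks, 1L)
      sort(runif(k, 1200, 4500))
    })
    intensity <- lapply(mz, function(m) runif(length(m), 0, 100))
    msi_dataset(coords, mz, intensity, grid_shape = c(rows, cols),
                sample_id = paste0("rand", seed))
  })
}

# brute-force oracle for ion-image extraction: plain double loop
oracle_ion_image <- function(dataset, target_mz, tolerance) {
  vals <- matrix(NA_real_, dataset$grid_shape[1L], dataset$grid_shape[2L])
  for (i in seq_len(nrow(dataset$coords))) {
    s <- 0
    for (j in seq_along(dataset$mz[[i]])) {
      if (abs(dataset$mz[[i]][j] - target_mz) <= tolerance) {
        s <- s + dataset$intensity[[i]][j]
      }
    }
    vals[dataset$coords$y[i] + 1L, dataset$coords$x[i] + 1L] <- s
  }
  vals
}

# brute-force oracle for border distance: exhaustive nearest-background
# search, grid edge treated as a ring of background pixels
oracle_border_distance <- function(tissue) {
  rows <- nrow(tissue); cols <- ncol(tissue)
  pad <- matrix(FALSE, rows + 2L, cols + 2L)
  pad[2:(rows + 1L), 2:(cols + 1L)] <- tissue
  bg <- which(!pad, arr.ind = TRUE)
  out <- matrix(NA_real_, rows, cols)
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      if (!tissue[r, cc]) next
      out[r, cc] <- sqrt(min((bg[, 1L] - (r + 1L))^2 + (bg[, 2L] - (cc + 1L))^2))
    }
  }
  out
}

# noise-free calibration parameters (exactness tests)
noise_free_calib <- function(seed = 1) {
  calib_sim_params(exp_sd = 0, pixel_sd = 0, batch_sd = 0,
                   background_mu = 0, background_sigma = 1e-9,
                   melittin_sigma = 0, seed = seed)
}

# a small log_ion_image wrapping a plain matrix
wrap_log_image <- function(values, sample_id = "t") {
  log_ion_image(values, pseudocount = 1, sample_id = sample_id)
}
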