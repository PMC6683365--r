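test_that("ion-image extraction equals brute-force summation over peak lists", {
  for (seed in 1:20) {
    d <- random_peak_dataset(seed, drop_pixels = seed %% 3L)
    target <- 1300 + (seed * 157) %% 3000
    tol <- c(0.5, 1, 5)[seed %% 3L + 1L]
    img <- extract_ion_image(d, target, tol)
    expect_identical(img$values, oracle_ion_image(d, target, tol))
  }
})

test_that("extraction window is closed on both sides and sums peaks", {
  d <- msi_dataset(
    data.frame(x = 0:2, y = c(0L, 0L, 0L)),
    mz = list(c(3617, 3619), c(3617.5, 3618.5), 2000),
    intensity = list(c(2, 3), c(5, 7), 10),
    grid_shape = c(1L, 3L))
  img <- extract_ion_image(d, 3618, 1)
  # peaks exactly at target +/- tolerance are included
  expect_equal(img$values[1, 1], 5)
  # two in-window peaks sum
  expect_equal(img$values[1, 2], 12)
  # no peak in window -> 0, not NA
  expect_equal(img$values[1, 3], 0)
})

test_that("disjoint windows covering the acquisition range reconstruct the TIC", {
  d <- random_peak_dataset(5, rows = 3L, cols = 3L)
  edges <- seq(1200, 4500, length.out = 12L)
  total <- matrix(0, 3, 3)
  for (k in seq_len(length(edges) - 1L)) {
    ctr <- (edges[k] + edges[k + 1L]) / 2
    # half-open windows via a tiny shrink at the right edge keep peaks from
    # double-counting except exactly at internal edges (none here)
    img <- extract_ion_image(d, ctr, tolerance = diff(edges[k:(k + 1L)]) / 2)
    total <- total + img$values
  }
  tic <- total_ion_current(d)
  expect_equal(total, tic$values, tolerance = 1e-12)
})

test_that("extraction warns outside the acquisition range and rejects bad tolerance", {
  d <- random_peak_dataset(1)
  expect_warning(extract_ion_image(d, 900, 1), "acquisition range")
  expect_error(extract_ion_image(d, 3618, 0), "tolerance")
})

test_that("imzML round trip preserves the dataset in processed mode", {
  d <- generate_section(section_sim_params(grid_shape = c(8L, 9L), seed = 11))
  tdir <- withr::local_tempdir()
  path <- file.path(tdir, "sec.imzML")
  files <- write_imzml(d, path, mode = "processed")
  expect_true(all(file.exists(files)))
  d2 <- read_imzml(path, group = d$group)
  expect_equal(d2$coords, d$coords)
  expect_equal(d2$grid_shape, d$grid_shape)
  expect_equal(d2$sample_id, d$sample_id)
  for (i in seq_len(n_pixels(d))) {
    expect_identical(d2$mz[[i]], d$mz[[i]])  # m/z stored as float64: exact
    expect_equal(d2$intensity[[i]], d$intensity[[i]], tolerance = 1e-6)
  }
})

test_that("continuous and processed encodings give identical ion images", {
  # shared m/z axis so both modes can encode the same data
  axis <- seq(1200, 4500, by = 150)
  coords <- expand.grid(x = 0:3, y = 0:2)
  ints <- surfmsi:::with_preserved_seed(3, {
    lapply(seq_len(nrow(coords)), function(i) runif(length(axis), 0, 50))
  })
  d <- msi_dataset(coords, rep(list(axis), nrow(coords)), ints,
                   grid_shape = c(3L, 4L))
  tdir <- withr::local_tempdir()
  write_imzml(d, file.path(tdir, "c.imzML"), mode = "continuous")
  write_imzml(d, file.path(tdir, "p.imzML"), mode = "processed")
  dc <- read_imzml(file.path(tdir, "c.imzML"))
  dp <- read_imzml(file.path(tdir, "p.imzML"))
  i1 <- extract_ion_image(dc, 3600, 200)
  i2 <- extract_ion_image(dp, 3600, 200)
  expect_equal(i1$values, i2$values)
})

test_that("a one-pixel one-peak file survives the round trip", {
  d <- msi_dataset(data.frame(x = 0L, y = 0L), list(3618.0), list(10.0),
                   grid_shape = c(1L, 1L))
  tdir <- withr::local_tempdir()
  write_imzml(d, file.path(tdir, "one.imzML"))
  d2 <- read_imzml(file.path(tdir, "one.imzML"))
  expect_equal(n_pixels(d2), 1L)
  expect_identical(d2$mz[[1]], 3618.0)
  expect_equal(d2$intensity[[1]], 10.0)
})

test_that("missing pixels are preserved as missing across the round trip", {
  d <- random_peak_dataset(9, rows = 5L, cols = 4L, drop_pixels = 3L)
  tdir <- withr::local_tempdir()
  write_imzml(d, file.path(tdir, "gap.imzML"))
  d2 <- read_imzml(file.path(tdir, "gap.imzML"))
  key <- function(x) sort(paste(x$coords$x, x$coords$y))
  expect_identical(key(d2), key(d))
  img <- extract_ion_image(d2, 2000, 100)
  expect_equal(sum(is.na(img$values)), 3L)
})

test_that("reader rejects a missing ibd, a tampered UUID and a bad checksum", {
  d <- random_peak_dataset(2)
  tdir <- withr::local_tempdir()
  path <- file.path(tdir, "x.imzML")
  write_imzml(d, path)
  expect_error(read_imzml(file.path(tdir, "nope.imzML")), "not found")

  file.copy(path, file.path(tdir, "orphan.imzML"))
  expect_error(read_imzml(file.path(tdir, "orphan.imzML")), "binary companion")

  # tamper with the ibd UUID
  ibd <- file.path(tdir, "x.ibd")
  raw <- readBin(ibd, "raw", file.size(ibd))
  raw[1:16] <- as.raw(0:15)
  writeBin(raw, ibd)
  expect_error(read_imzml(path), "UUID mismatch")

  # restore UUID but corrupt a data byte: checksum must catch it
  write_imzml(d, path)
  raw <- readBin(ibd, "raw", file.size(ibd))
  raw[length(raw)] <- as.raw(255L)
  writeBin(raw, ibd)
  expect_error(read_imzml(path), "MD5")
})

test_that("the dataset constructor enforces its invariants", {
  expect_error(msi_dataset(data.frame(x = integer(), y = integer()),
                           list(), list(), c(1L, 1L)), "at least one pixel")
  expect_error(
    msi_dataset(data.frame(x = 0L, y = 0L), list(c(2000, 1500)), list(c(1, 1)),
                c(1L, 1L)),
    "ascending")
  expect_error(
    msi_dataset(data.frame(x = c(0L, 0L), y = c(0L, 0L)),
                list(1500, 1500), list(1, 1), c(1L, 1L)),
    "duplicate")
  expect_error(
    msi_dataset(data.frame(x = 5L, y = 0L), list(1500), list(1), c(1L, 2L)),
    "outside grid")
})

test_that("an independent Python imzML parser reads the written files", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  have <- system2(py, c("-c", shQuote("import pyimzml")),
                  stdout = NULL, stderr = NULL)
  skip_if(have != 0L, "pyimzml not importable")
  d <- msi_dataset(data.frame(x = c(0L, 1L), y = c(0L, 0L)),
                   list(c(1500, 3618), c(2000.5, 3886)),
                   list(c(4, 8), c(1.5, 2.25)),
                   grid_shape = c(1L, 2L))
  tdir <- withr::local_tempdir()
  path <- file.path(tdir, "py.imzML")
  write_imzml(d, path)
  script <- paste(
    "from pyimzml.ImzMLParser import ImzMLParser",
    sprintf("p = ImzMLParser(r'%s')", path),
    "for i, c in enumerate(p.coordinates):",
    "    mz, it = p.getspectrum(i)",
    "    print(c[0], c[1], ' '.join(f'{v:.6f}' for v in mz),",
    "          ' '.join(f'{v:.6f}' for v in it))",
    sep = "\n")
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  expect_length(out, 2L)
  f1 <- strsplit(out[1L], " +")[[1L]]
  expect_equal(as.numeric(f1[1:2]), c(1, 1))          # 1-based position
  expect_equal(as.numeric(f1[3:4]), c(1500, 3618))    # m/z exact
  expect_equal(as.numeric(f1[5:6]), c(4, 8), tolerance = 1e-6)
})
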