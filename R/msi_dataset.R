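#' Pixel-indexed MSI dataset
#'
#' The unit of I/O for the pipeline: one object per lung section or
#' calibration slide.  Each pixel holds a sparse (processed-mode style)
#' peak list: a strictly ascending m/z vector and a matching non-negative
#' intensity vector.  Coordinates are 0-based with `x` the column and `y`
#' the row of a row-major grid; imzML's 1-based indices are converted on
#' read/write.
#'
#' @param coords data frame with integer columns `x`, `y` (0-based).
#' @param mz list of numeric vectors, one per pixel, strictly ascending.
#' @param intensity list of numeric vectors, same lengths as `mz`, all >= 0.
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param pixel_pitch pixel spacing in micrometres (raster step).
#' @param sample_id sample identifier string.
#' @param group one of `"treated"`, `"control"`, `"calibration"`.
#'
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensity, grid_shape,
                        pixel_pitch = 350, sample_id = "sample",
                        group = c("treated", "control", "calibration")) {
  group <- match.arg(group)
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  n <- nrow(coords)
  if (n == 0L) stop("msi_dataset must contain at least one pixel")
  if (length(mz) != n || length(intensity) != n) {
    stop("mz and intensity must have one entry per pixel")
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L)) {
    stop("grid_shape must be two positive integers (rows, cols)")
  }
  if (any(coords$x < 0L) || any(coords$x >= grid_shape[2L]) ||
      any(coords$y < 0L) || any(coords$y >= grid_shape[1L])) {
    stop("pixel coordinates outside grid: need 0 <= x < cols, 0 <= y < rows")
  }
  if (anyDuplicated(coords[, c("x", "y")])) {
    stop("duplicate pixel coordinates")
  }
  for (i in seq_len(n)) {
    mi <- mz[[i]]; ii <- intensity[[i]]
    if (length(mi) != length(ii)) {
      stop(sprintf("pixel %d (x=%d, y=%d): mz and intensity lengths differ",
                   i, coords$x[i], coords$y[i]))
    }
    if (length(mi) > 1L && any(diff(mi) <= 0)) {
      stop(sprintf("pixel %d (x=%d, y=%d): m/z values not strictly ascending",
                   i, coords$x[i], coords$y[i]))
    }
    if (any(ii < 0)) {
      stop(sprintf("pixel %d (x=%d, y=%d): negative intensity",
                   i, coords$x[i], coords$y[i]))
    }
  }
  structure(
    list(coords = coords[, c("x", "y")],
         mz = mz, intensity = intensity,
         grid_shape = grid_shape,
         pixel_pitch = pixel_pitch,
         sample_id = sample_id,
         group = group),
    class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %s (%s)\n", x$sample_id, x$group))
  cat(sprintf("  grid: %d x %d pixels @ %g um, %d pixels acquired\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_pitch,
              nrow(x$coords)))
  np <- lengths(x$mz)
  cat(sprintf("  peaks per pixel: %d-%d (median %g)\n",
              min(np), max(np), stats::median(np)))
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param dataset an `msi_dataset`.
#' @return integer pixel count.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' 2D ion image
#'
#' Intensity of one target ion over the acquisition grid.  `values` is a
#' rows x cols matrix; pixels never acquired are `NA` (distinct from a true
#' zero, which means no peak fell in the extraction window).
#'
#' @param values numeric matrix, rows x cols.
#' @param target_mz target m/z in Da.
#' @param tolerance half-width of the extraction window in Da.
#' @param sample_id,group carried over from the source dataset.
#' @return An object of class `ion_image`.
#' @export
ion_image <- function(values, target_mz, tolerance,
                      sample_id = "sample", group = "treated") {
  stopifnot(is.matrix(values))
  if (any(values < 0, na.rm = TRUE)) stop("ion image intensities must be >= 0")
  structure(
    list(values = values, target_mz = target_mz, tolerance = tolerance,
         sample_id = sample_id, group = group),
    class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %g +/- %g, %d x %d grid (%d missing)\n",
              x$target_mz, x$tolerance, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Log10-transformed ion image
#'
#' @param values matrix of log10-transformed intensities.
#' @param pseudocount the positive constant added before taking log10.
#' @param target_mz,tolerance,sample_id,group carried over.
#' @return An object of class `log_ion_image`.
#' @export
log_ion_image <- function(values, pseudocount, target_mz = NA_real_,
                          tolerance = NA_real_, sample_id = "sample",
                          group = "treated") {
  stopifnot(is.matrix(values), pseudocount > 0)
  structure(
    list(values = values, pseudocount = pseudocount,
         target_mz = target_mz, tolerance = tolerance,
         sample_id = sample_id, group = group),
    class = "log_ion_image")
}

#' @export
print.log_ion_image <- function(x, ...) {
  cat(sprintf(
    "<log_ion_image> m/z %g, %d x %d grid, pseudocount %g\n",
    x$target_mz, nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}
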