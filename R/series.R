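#' 4D BOLD-like time series
#'
#' Container for a voxel grid sampled over time: a 4D array (x, y, z, t)
#' together with its repetition time. All pipeline stages consume and return
#' this class.
#'
#' @param data numeric 4D array, dimensions `c(nx, ny, nz, n_timepoints)`.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param voxel_mm edge length of an isotropic voxel in millimetres
#'   (metadata only).
#' @return An object of class `series4d`.
#' @export
series4d <- function(data, tr_seconds, voxel_mm = 3) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a single positive number")
  if (dim(data)[4] < 1L) stop("series must contain at least one timepoint")
  if (!all(is.finite(data))) stop("series contains non-finite values")
  structure(
    list(data = data, tr_seconds = tr_seconds, voxel_mm = voxel_mm),
    class = "series4d"
  )
}

#' @export
print.series4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<series4d> grid %dx%dx%d, %d timepoints, TR = %g s\n",
    d[1], d[2], d[3], d[4], x$tr_seconds
  ))
  invisible(x)
}

#' @export
dim.series4d <- function(x) dim(x$data)

n_timepoints <- function(series) dim(series$data)[4]

grid_dims <- function(series) dim(series$data)[1:3]

#' Extract the time x voxel matrix of a series
#'
#' @param series a [series4d].
#' @param voxels optional integer vector of linear voxel indices within the
#'   3D grid; defaults to all voxels.
#' @return numeric matrix, timepoints x voxels.
#' @export
series_matrix <- function(series, voxels = NULL) {
  d <- dim(series$data)
  nt <- d[4]
  m <- matrix(series$data, nrow = prod(d[1:3]), ncol = nt)
  if (!is.null(voxels)) m <- m[voxels, , drop = FALSE]
  t(m)
}

#' Rebuild a series4d from a time x voxel matrix
#'
#' Inverse of [series_matrix()] for the full grid: columns are laid back into
#' the 3D grid in linear index order.
#'
#' @param x timepoints x voxels matrix covering the whole grid.
#' @param template a [series4d] providing grid geometry and TR.
#' @return a [series4d].
#' @export
matrix_to_series <- function(x, template) {
  d3 <- grid_dims(template)
  if (ncol(x) != prod(d3)) stop("column count does not match the template grid")
  arr <- array(t(x), dim = c(d3, nrow(x)))
  series4d(arr, template$tr_seconds, template$voxel_mm)
}
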