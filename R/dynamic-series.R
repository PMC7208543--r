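#' Dynamic diffusion-weighted image series
#'
#' A `dynamic_series` holds a single-slice dynamic scan: a stack of 2D
#' diffusion-weighted images acquired once per repetition time while the
#' stimulation current is varied. It is the universal input of the pipeline.
#'
#' @param pixels Numeric 3D array `(row, col, dynamic)` of non-negative signal
#'   intensities in arbitrary scanner units.
#' @param voxel_size_mm Length-2 numeric, in-plane voxel dimensions
#'   `(row_mm, col_mm)`.
#' @param slice_thickness_mm Scalar slice thickness in mm.
#' @param tr_s Repetition time in seconds; one dynamic is acquired per TR.
#'
#' @return An object of class `dynamic_series`: a list with elements
#'   `pixels`, `voxel_size_mm`, `slice_thickness_mm` and `tr_s`.
#' @examples
#' s <- dynamic_series(array(100, dim = c(8, 8, 4)))
#' n_dynamics(s)
#' @export
dynamic_series <- function(pixels, voxel_size_mm = c(1.5, 1.5),
                           slice_thickness_mm = 7.5, tr_s = 1.0) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop_format("`pixels` must be a 3D array (row, col, dynamic)")
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop_format("series intensities must be finite")
  }
  if (any(pixels < 0)) stop_format("series intensities must be non-negative")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 2L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop_format("`voxel_size_mm` must be two positive values")
  }
  if (dim(pixels)[3] < 1L) stop_format("a series needs at least one dynamic")
  structure(
    list(pixels = pixels, voxel_size_mm = voxel_size_mm,
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         tr_s = as.numeric(tr_s)),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<dynamic_series> %d x %d voxels, %d dynamics | voxel %.2g x %.2g mm, slice %.2g mm, TR %.3g s\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
    x$slice_thickness_mm, x$tr_s))
  invisible(x)
}

#' Number of dynamics in a series
#' @param series A [dynamic_series()].
#' @return Integer count of dynamics (time points).
#' @export
n_dynamics <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  dim(series$pixels)[3]
}

#' Read and write dynamic series as NIfTI
#'
#' The series is stored as a 4D NIfTI-1 volume `(row, col, 1, dynamic)` with
#' the in-plane voxel size and slice thickness in `pixdim[1:3]` and the TR in
#' `pixdim[4]`. Data are written as float64 so that a write/read round trip
#' is bit-identical.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `load_dynamic_series()` returns a [dynamic_series()];
#'   `write_dynamic_series()` returns `path` invisibly.
#' @export
load_dynamic_series <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    stop_format("expected a 3D or 4D NIfTI volume with dynamics on the last axis")
  }
  # raw header pixdim (from the file: the in-memory image sanitises zeros);
  # index 1 is qfac, 2:4 spatial, 5 temporal
  pd <- RNifti::niftiHeader(path)$pixdim[seq_len(length(d)) + 1L]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(d) == 4L) {
    if (d[3] != 1L) stop_format("multi-slice volumes are not supported; one slice per file")
    arr <- array(arr, dim = d[c(1, 2, 4)])
    vox <- pd[1:2]; thick <- pd[3]
    tr <- if (length(pd) >= 4) pd[4] else 1.0
  } else {
    vox <- pd[1:2]; thick <- 7.5
    tr <- if (length(pd) >= 3) pd[3] else 1.0
  }
  if (any(!is.finite(vox)) || any(vox <= 0)) {
    stop_format("NIfTI header has missing or zero pixel dimensions")
  }
  if (!is.finite(tr) || tr <= 0) tr <- 1.0
  dynamic_series(arr, voxel_size_mm = vox, slice_thickness_mm = thick, tr_s = tr)
}

#' @rdname load_dynamic_series
#' @param series A [dynamic_series()].
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$pixels)
  arr <- array(series$pixels, dim = c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$slice_thickness_mm,
                           series$tr_s)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
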