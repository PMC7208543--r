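#' Muscle label masks
#'
#' A `muscle_mask` is an integer label image delineating the muscles
#' activated by the stimulated nerve: 0 is background (and any muscle not of
#' interest), label `k > 0` is one muscle. For fibular-nerve studies the
#' typical label set is TA, EDL, PL; for tibial-nerve studies SOL, GM, GL.
#'
#' @param labels Integer-valued 2D matrix of labels.
#' @param names Named character vector mapping label values to muscle names,
#'   e.g. `c("1" = "TA", "2" = "EDL", "3" = "PL")`. Every nonzero label
#'   occurring in `labels` must be named.
#' @return An object of class `muscle_mask`: list with `labels` (integer
#'   matrix) and `names`.
#' @examples
#' m <- muscle_mask(matrix(c(0, 1, 1, 0), 2, 2), c("1" = "TA"))
#' @export
muscle_mask <- function(labels, names = character()) {
  if (!is.matrix(labels)) stop_format("`labels` must be a 2D matrix")
  if (anyNA(labels) || any(!is.finite(labels))) {
    stop_format("mask labels must be finite")
  }
  if (any(labels != round(labels))) {
    stop_format("mask labels must be integer-valued")
  }
  lab <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(lab < 0)) stop_format("mask labels must be non-negative")
  present <- sort(unique(lab[lab > 0L]))
  named <- suppressWarnings(as.integer(base::names(names)))
  missing <- setdiff(present, named)
  if (length(missing) > 0L) {
    stop_consistency(sprintf("unnamed mask label(s): %s",
                             paste(missing, collapse = ", ")))
  }
  structure(list(labels = lab, names = names), class = "muscle_mask")
}

#' @export
print.muscle_mask <- function(x, ...) {
  present <- sort(unique(x$labels[x$labels > 0L]))
  nm <- if (length(present)) {
    paste(sprintf("%d=%s", present, x$names[as.character(present)]),
          collapse = ", ")
  } else "empty"
  cat(sprintf("<muscle_mask> %d x %d | %s\n",
              nrow(x$labels), ncol(x$labels), nm))
  invisible(x)
}

#' Read and write muscle masks
#'
#' Masks are stored as 2D NIfTI label images (or 8-bit grayscale PNG, where
#' pixel values are the labels). Label names are supplied by the caller, as
#' image formats carry no label legend.
#'
#' @param path Path to a `.nii`/`.nii.gz` or `.png` file.
#' @param names Named character vector, label value to muscle name.
#' @return `load_mask()` returns a [muscle_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
load_mask <- function(path, names = character()) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lab <- round(img * 255)
  } else {
    img <- RNifti::readNifti(path)
    lab <- as.array(img)
    attributes(lab) <- list(dim = dim(lab))
    d <- dim(lab)
    if (length(d) > 2L) {
      if (prod(d[-(1:2)]) != 1L) stop_format("mask must be a single 2D slice")
      lab <- array(lab, dim = d[1:2])
    }
    if (max(abs(lab - round(lab))) > 1e-6) {
      stop_format("mask image contains non-integer values")
    }
  }
  muscle_mask(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)), names)
}

#' @rdname load_mask
#' @param mask A [muscle_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "muscle_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(mask$labels) > 255L) stop_format("PNG masks support labels up to 255")
    png::writePNG(mask$labels / 255, path)
  } else {
    img <- RNifti::asNifti(mask$labels)
    RNifti::writeNifti(img, path, datatype = "int16")
  }
  invisible(path)
}

#' Check joint consistency of series, mask and schedule
#'
#' Validates that a mask matches the in-plane shape of a series and that a
#' schedule covers exactly the series' dynamics.
#'
#' @param series A [dynamic_series()].
#' @param mask Optional [muscle_mask()].
#' @param schedule Optional [stim_schedule()].
#' @return `TRUE` invisibly; otherwise a consistency error is thrown.
#' @export
check_consistency <- function(series, mask = NULL, schedule = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$pixels)
  if (!is.null(mask)) {
    if (!all(dim(mask$labels) == d[1:2])) {
      stop_consistency(sprintf(
        "mask shape %d x %d does not match series %d x %d",
        nrow(mask$labels), ncol(mask$labels), d[1], d[2]))
    }
  }
  if (!is.null(schedule)) {
    if (nrow(schedule) != d[3]) {
      stop_consistency(sprintf(
        "schedule has %d dynamics but series has %d", nrow(schedule), d[3]))
    }
  }
  invisible(TRUE)
}
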