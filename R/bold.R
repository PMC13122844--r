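#' BOLD time series for one subject
#'
#' Container for a subject's in-mask fMRI time series: a T x V matrix with
#' one row per acquired volume (acquisition order) and one column per
#' voxel, plus the voxel coordinates, repetition time and grid metadata.
#' Columns follow the lexicographic order of `voxel_index`.
#'
#' @param subject_id character subject identifier.
#' @param data numeric T x V matrix (time points x voxels), all finite,
#'   T >= 2.
#' @param voxel_index integer V x 3 matrix of 0-based grid coordinates, one
#'   row per column of `data`; must be unique and inside `grid$shape`.
#' @param tr_s positive repetition time in seconds (2 s in the study this
#'   package emulates).
#' @param grid a [volume_grid()].
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(subject_id, data, voxel_index, tr_s, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    fp_stop("funcphen_bad_bold", "data must be a finite numeric matrix")
  if (nrow(data) < 2L)
    fp_stop("funcphen_bad_bold", "need at least 2 time points")
  voxel_index <- matrix(as.integer(voxel_index), ncol = 3L)
  if (nrow(voxel_index) != ncol(data))
    fp_stop("funcphen_bad_bold",
            "voxel_index rows (%d) must match data columns (%d)",
            nrow(voxel_index), ncol(data))
  if (any(voxel_index < 0L) || any(t(voxel_index) >= grid$shape))
    fp_stop("funcphen_bad_bold", "voxel_index outside grid")
  if (anyDuplicated(voxel_index))
    fp_stop("funcphen_bad_bold", "duplicate voxel coordinates")
  tr_s <- as.numeric(tr_s)
  if (length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    fp_stop("funcphen_bad_bold", "tr_s must be a positive real")
  structure(list(subject_id = as.character(subject_id), data = data,
                 voxel_index = voxel_index, tr_s = tr_s, grid = grid),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> subject '%s': %d time points x %d voxels, TR %.3g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

#' Number of time points / voxels of a BOLD series
#' @param series a [bold_series()].
#' @return integer.
#' @export
n_timepoints <- function(series) nrow(series$data)

#' @rdname n_timepoints
#' @export
n_voxels <- function(series) ncol(series$data)

#' Replace the data matrix, keeping metadata
#' @keywords internal
#' @noRd
bold_with_data <- function(series, data, subject_id = series$subject_id) {
  out <- series
  out$data <- data
  out$subject_id <- subject_id
  out
}

#' Restrict a BOLD series to the voxels of a mask
#'
#' @param series a [bold_series()].
#' @param mask an [roi_mask()] whose voxels are all present in the series.
#' @return a [bold_series()] with columns reduced to the mask voxels, in
#'   the mask's lexicographic order.
#' @export
mask_bold <- function(series, mask) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pos <- match(key(mask$voxel_index), key(series$voxel_index))
  if (anyNA(pos))
    fp_stop("funcphen_mask_out_of_bounds",
            "mask '%s' has voxels not covered by the series", mask$label)
  out <- series
  out$data <- series$data[, pos, drop = FALSE]
  out$voxel_index <- series$voxel_index[pos, , drop = FALSE]
  out
}
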