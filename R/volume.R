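#' Volume grid: the coordinate frame of a voxel array
#'
#' Describes the 3-D sampling grid of a BOLD volume: its shape in voxels,
#' the voxel size in mm, and the 4x4 affine mapping 0-based voxel indices
#' to world coordinates in mm. The study data this mirrors were acquired at
#' 1.5 mm isotropic resolution; the grid is fully configurable.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric length 3, positive voxel edge lengths.
#' @param affine 4x4 numeric matrix; if `NULL`, a diagonal affine built
#'   from `voxel_size_mm` is used.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(1.5, 1.5, 1.5), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    fp_stop("funcphen_bad_grid", "shape must be 3 positive integers")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    fp_stop("funcphen_bad_grid", "voxel_size_mm must be 3 positive reals")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    fp_stop("funcphen_bad_grid", "affine must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    fp_stop("funcphen_bad_grid", "affine must be invertible")
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(colnorm - voxel_size_mm) > 1e-6))
    fp_stop("funcphen_bad_grid",
            "voxel_size_mm inconsistent with affine column norms")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Order voxel indices lexicographically
#'
#' Masks are unordered voxel sets; all serialization and matrix column
#' ordering uses lexicographic (i, j, k) order so that column order is
#' deterministic across runs.
#'
#' @param idx integer matrix, one 0-based (i, j, k) triple per row.
#' @return the row-permuted matrix.
#' @keywords internal
lex_order_voxels <- function(idx) {
  idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
}

#' Linear (column-major) position of voxel triples in a grid
#' @keywords internal
#' @noRd
voxel_linear_index <- function(idx, shape) {
  1L + idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3])
}

#' Region-of-interest mask
#'
#' A labelled, unordered set of voxels on a [volume_grid()]. Rows are stored
#' in lexicographic index order (see [lex_order_voxels()]).
#'
#' @param label character label, e.g. a movement condition (`"LH"`) or a
#'   composite name (`"combined"`).
#' @param voxel_index integer matrix, one 0-based (i, j, k) triple per row.
#' @param grid a [volume_grid()].
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(label, voxel_index, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  voxel_index <- matrix(as.integer(voxel_index), ncol = 3L)
  if (nrow(voxel_index) == 0L)
    fp_stop("funcphen_empty_mask", "mask '%s' has no voxels", label)
  if (any(voxel_index < 0L) ||
      any(t(voxel_index) >= grid$shape))
    fp_stop("funcphen_mask_out_of_bounds",
            "mask '%s' has voxels outside the grid", label)
  voxel_index <- lex_order_voxels(voxel_index)
  if (anyDuplicated(voxel_index))
    fp_stop("funcphen_bad_mask", "mask '%s' has duplicate voxels", label)
  structure(list(label = as.character(label), voxel_index = voxel_index,
                 grid = grid),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s', %d voxels\n", x$label, nrow(x$voxel_index)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask an [roi_mask()].
#' @return integer voxel count.
#' @export
mask_size <- function(mask) nrow(mask$voxel_index)

#' Voxel-wise scalar maps
#'
#' `scalar_map()` builds a generic voxel-aligned map; `t_map()`, `ec_map()`
#' and `seed_map()` are typed variants for GLM t-statistics, eigenvector
#' centrality and seed correlation values. An `ec_map` must be non-negative
#' with unit Euclidean norm.
#'
#' @param values numeric vector, one value per voxel of `voxel_index`.
#' @param voxel_index integer matrix of 0-based voxel triples aligned with
#'   `values` (typically a mask's `voxel_index`).
#' @param label character label.
#' @param kind map subclass: `"t_map"`, `"ec_map"` or `"seed_map"`.
#' @return an object of class `c(kind, "scalar_map")`.
#' @export
scalar_map <- function(values, voxel_index, label, kind = "scalar_map") {
  values <- as.numeric(values)
  voxel_index <- matrix(as.integer(voxel_index), ncol = 3L)
  if (length(values) != nrow(voxel_index))
    fp_stop("funcphen_bad_map", "values and voxel_index lengths differ")
  if (!all(is.finite(values)))
    fp_stop("funcphen_bad_map", "map '%s' has non-finite values", label)
  if (kind == "ec_map") {
    if (any(values < -1e-12))
      fp_stop("funcphen_bad_map", "ec_map must be non-negative")
    if (abs(sqrt(sum(values^2)) - 1) > 1e-8)
      fp_stop("funcphen_bad_map", "ec_map must have unit Euclidean norm")
  }
  cls <- unique(c(kind, "scalar_map"))
  structure(list(values = values, voxel_index = voxel_index,
                 label = as.character(label)),
            class = cls)
}

#' @rdname scalar_map
#' @export
t_map <- function(values, voxel_index, label)
  scalar_map(values, voxel_index, label, "t_map")

#' @rdname scalar_map
#' @export
ec_map <- function(values, voxel_index, label)
  scalar_map(values, voxel_index, label, "ec_map")

#' @rdname scalar_map
#' @export
seed_map <- function(values, voxel_index, label)
  scalar_map(values, voxel_index, label, "seed_map")

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<%s> '%s', %d voxels, range [%.4g, %.4g]\n", class(x)[1],
              x$label, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
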