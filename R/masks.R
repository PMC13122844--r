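#' Top-k voxel mask from a t-map
#'
#' Selects the `k` voxels with the largest t values (fixed-size localizer
#' masks: every ROI gets the same size, so subjects with weaker responses
#' are not disadvantaged). Ties at the boundary are broken by
#' lexicographic voxel index, which makes the selection deterministic.
#'
#' @param tmap a [t_map()] (any [scalar_map()] works).
#' @param k number of voxels to keep (1500 in the emulated study).
#' @param grid the [volume_grid()] the map lives on.
#' @return an [roi_mask()] of exactly `k` voxels labelled like the map.
#' @export
top_k_mask <- function(tmap, k = 1500L, grid) {
  v <- length(tmap$values)
  if (k > v)
    fp_stop("funcphen_k_too_large", "k (%d) exceeds voxel count (%d)", k, v)
  idx <- tmap$voxel_index
  o <- order(-tmap$values, idx[, 1], idx[, 2], idx[, 3])
  roi_mask(tmap$label, idx[o[seq_len(k)], , drop = FALSE], grid)
}

# 26- or 6-neighbourhood offsets (positive half, each pair counted once)
.neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1L, , drop = FALSE]
  # keep one of each (o, -o) pair
  keep <- off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
    (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0)
  off[keep, , drop = FALSE]
}

#' Connected components of a voxel set
#'
#' @param idx integer matrix of voxel triples.
#' @param connectivity 26 (faces, edges, corners; default) or 6 (faces).
#' @return integer component label per row of `idx`.
#' @keywords internal
#' @export
voxel_components <- function(idx, connectivity = 26L) {
  n <- nrow(idx)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  offsets <- .neighbour_offsets(connectivity)
  edges <- NULL
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    nb <- sweep(idx, 2L, -off)
    hit <- match(paste(nb[, 1], nb[, 2], nb[, 3]), key)
    found <- which(!is.na(hit))
    if (length(found))
      edges <- rbind(edges, cbind(found, hit[found]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Group-level mask: intersection then largest connected cluster
#'
#' Intersects per-subject masks (keeping only voxels active in every
#' subject) and then retains the largest connected component of the
#' intersection. If several components tie in size, the one containing
#' the lexicographically smallest voxel wins.
#'
#' @param masks list of [roi_mask()] objects on one shared grid.
#' @param connectivity component neighbourhood, 26 (default) or 6.
#' @return an [roi_mask()] labelled like the first input.
#' @export
group_mask <- function(masks, connectivity = 26L) {
  stopifnot(length(masks) >= 1L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  inter <- key(masks[[1]]$voxel_index)
  for (m in masks[-1]) inter <- intersect(inter, key(m$voxel_index))
  if (length(inter) == 0L)
    fp_stop("funcphen_empty_intersection",
            paste("mask intersection for '%s' is empty; consider fewer",
                  "subjects or a larger top-k"), masks[[1]]$label)
  pos <- match(inter, key(masks[[1]]$voxel_index))
  idx <- lex_order_voxels(masks[[1]]$voxel_index[pos, , drop = FALSE])
  comp <- voxel_components(idx, connectivity)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # idx is in lexicographic order, so the tied component whose first
    # member appears earliest contains the smallest voxel
    first_row <- vapply(best, function(b) min(which(comp == b)), integer(1))
    best <- best[which.min(first_row)]
  }
  roi_mask(masks[[1]]$label, idx[comp == best, , drop = FALSE],
           masks[[1]]$grid)
}

#' Union of condition masks
#'
#' @param group_masks list of [roi_mask()] objects on one shared grid.
#' @param label label of the union (default `"combined"`).
#' @return an [roi_mask()].
#' @export
combined_mask <- function(group_masks, label = "combined") {
  stopifnot(length(group_masks) >= 1L)
  idx <- unique(do.call(rbind, lapply(group_masks, `[[`, "voxel_index")))
  roi_mask(label, idx, group_masks[[1]]$grid)
}
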