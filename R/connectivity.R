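#' Eigenvector centrality map of in-mask voxels
#'
#' Scores each voxel's network hubness as its entry in the principal
#' eigenvector of a non-negative voxel-similarity matrix. Similarity is
#' `(r + 1)/2` by default, with `r` the Pearson correlation of voxel time
#' courses: strictly positive entries guarantee (Perron-Frobenius) a
#' unique non-negative principal eigenvector. `max(r, 0)` is available as
#' an alternative. Computed by power iteration to relative tolerance
#' 1e-10 (at most 1000 iterations).
#'
#' @param series a [bold_series()].
#' @param mask an [roi_mask()] with at least 2 voxels.
#' @param similarity `"shifted"` for `(r+1)/2` (default) or `"positive"`
#'   for `max(r, 0)`.
#' @param tol,max_iter power-iteration controls.
#' @return an [ec_map()] (non-negative, unit Euclidean norm), aligned with
#'   the mask's voxel order.
#' @export
ecm <- function(series, mask, similarity = c("shifted", "positive"),
                tol = 1e-10, max_iter = 1000L) {
  similarity <- match.arg(similarity)
  sub <- mask_bold(series, mask)
  v <- ncol(sub$data)
  if (v < 2L)
    fp_stop("funcphen_too_few_voxels", "ecm needs at least 2 in-mask voxels")
  sds <- apply(sub$data, 2L, stats::sd)
  if (any(sds == 0))
    fp_stop("funcphen_constant_column",
            "%d constant voxel time course(s) in mask '%s'",
            sum(sds == 0), mask$label)
  r <- stats::cor(sub$data)
  a <- if (similarity == "shifted") (r + 1) / 2 else pmax(r, 0)
  x <- rep(1 / sqrt(v), v)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ax <- as.numeric(a %*% x)
    x_new <- ax / sqrt(sum(ax^2))
    if (sqrt(sum((x_new - x)^2)) < tol * sqrt(sum(x_new^2))) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged)
    fp_stop("funcphen_no_convergence",
            "power iteration did not converge in %d iterations", max_iter)
  x <- pmax(x, 0)
  x <- x / sqrt(sum(x^2))
  ec_map(x, mask$voxel_index, paste0("ecm_", mask$label))
}

#' Seed-based correlation map
#'
#' The seed signal is the mean of the z-scored time courses of all mask
#' voxels within a Euclidean ball of `radius` voxels around
#' `seed_center`; the map value at each in-mask voxel is the Pearson
#' correlation between its z-scored time course and the z-scored seed
#' signal (computed as the dot product divided by T - 1).
#'
#' @param series a [bold_series()].
#' @param seed_center integer 3-vector, 0-based voxel index of the seed
#'   centre.
#' @param radius seed radius in voxel units (default 5; centre included).
#' @param mask an [roi_mask()] defining both the seed support and the
#'   mapped voxels.
#' @param label map label.
#' @return a [seed_map()] with values in `[-1, 1]`, aligned with the mask.
#' @export
seed_connectivity <- function(series, seed_center, radius = 5, mask,
                              label = NULL) {
  sub <- mask_bold(series, mask)
  d2 <- colSums((t(sub$voxel_index) - as.numeric(seed_center))^2)
  in_seed <- which(d2 <= radius^2 + 1e-9)
  if (length(in_seed) == 0L)
    fp_stop("funcphen_empty_seed",
            "no mask voxels within radius %g of the seed centre", radius)
  n_t <- nrow(sub$data)
  z <- .zscore_matrix(sub$data, "sample", warn_constant = FALSE)
  sds <- apply(sub$data, 2L, stats::sd)
  if (any(sds == 0))
    fp_stop("funcphen_constant_column",
            "constant voxel time course(s) in mask '%s'", mask$label)
  seed_sig <- rowMeans(z[, in_seed, drop = FALSE])
  if (stats::sd(seed_sig) == 0)
    fp_stop("funcphen_constant_column", "seed signal is constant")
  seed_z <- as.numeric(.zscore_matrix(matrix(seed_sig), "sample"))
  vals <- as.numeric(crossprod(z, seed_z)) / (n_t - 1)
  vals <- pmin(1, pmax(-1, vals))
  if (is.null(label))
    label <- sprintf("seed_%d_%d_%d", seed_center[1], seed_center[2],
                     seed_center[3])
  seed_map(vals, sub$voxel_index, label)
}

#' Stage-wise patient-minus-control connectivity contrast
#'
#' For every King's stage and seed label, the mean over patients of
#' (patient map mean - matched-control map mean), map means taken over
#' the mask the maps were computed on. The emulated study reports these
#' deltas as an inverted-U profile over stages 1-3.
#'
#' @param patient_maps nested list: `patient_maps[[patient_id]][[seed]]`
#'   is a [seed_map()].
#' @param control_maps nested list keyed by control id, same seed labels.
#' @param records clinical `data.frame` (needs `patient_id`,
#'   `kings_stage`).
#' @param matching named character vector mapping patient id to matched
#'   control id; `NULL` pairs patients and controls in list order (extra
#'   patients beyond the number of controls are unmatched and skipped).
#' @return `data.frame` with columns `stage`, `seed`, `delta`, `n`;
#'   stages with no matched patients are absent (with a warning).
#' @export
stage_contrast <- function(patient_maps, control_maps, records,
                           matching = NULL) {
  if (is.null(matching)) {
    n <- min(length(patient_maps), length(control_maps))
    matching <- stats::setNames(names(control_maps)[seq_len(n)],
                                names(patient_maps)[seq_len(n)])
  }
  seeds <- names(patient_maps[[1]])
  out <- NULL
  for (stage in 1:3) {
    pids <- records$patient_id[records$kings_stage == stage]
    pids <- pids[pids %in% names(matching) & pids %in% names(patient_maps)]
    if (length(pids) == 0L) {
      fp_warn("funcphen_empty_stage", "no matched patients in stage %d", stage)
      next
    }
    for (sd_lab in seeds) {
      deltas <- vapply(pids, function(p) {
        mean(patient_maps[[p]][[sd_lab]]$values) -
          mean(control_maps[[matching[[p]]]][[sd_lab]]$values)
      }, numeric(1))
      out <- rbind(out, data.frame(stage = stage, seed = sd_lab,
                                   delta = mean(deltas),
                                   n = length(deltas)))
    }
  }
  rownames(out) <- NULL
  out
}
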