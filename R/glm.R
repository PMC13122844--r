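#' First-level GLM for a block design
#'
#' Ordinary least squares per voxel with a design matrix of one
#' HRF-convolved boxcar per condition plus an intercept. Each condition's
#' t statistic tests that condition's amplitude against baseline
#' (contrast on the single regressor), with residual degrees of freedom
#' `T - rank(X)`. No autocorrelation correction is applied (a documented
#' deviation from SPM's prewhitening defaults).
#'
#' @param series a (band-passed) [bold_series()].
#' @param schedule the subject's [design_schedule()].
#' @return an object of class `glm_result`: `beta` (coefficients x
#'   voxels), `tmaps` (named list of [t_map()] per condition), `dof`,
#'   `sigma2` (residual variance per voxel).
#' @export
fit_glm <- function(series, schedule) {
  stopifnot(inherits(series, "bold_series"))
  y <- series$data
  n_t <- nrow(y)
  reg <- condition_regressors(schedule, n_t, series$tr_s)
  x <- cbind(intercept = 1, reg)
  if (n_t <= ncol(x))
    fp_stop("funcphen_series_too_short",
            "need more than %d time points for %d regressors", ncol(x), ncol(x))
  qx <- qr(x)
  if (qx$rank < ncol(x))
    fp_stop("funcphen_rank_deficient", "design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  res <- y - x %*% beta
  dof <- n_t - qx$rank
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qx))
  zero_vox <- colSums(y != 0) == 0L
  if (any(zero_vox))
    fp_warn("funcphen_degenerate_voxel",
            "%d all-zero voxel(s); their t set to 0", sum(zero_vox))
  tmaps <- list()
  for (cond in CONDITIONS) {
    j <- match(cond, colnames(x))
    se <- sqrt(pmax(sigma2, 1e-300) * xtx_inv[j, j])
    tv <- beta[j, ] / se
    tv[zero_vox] <- 0
    tmaps[[cond]] <- t_map(tv, series$voxel_index, cond)
  }
  structure(list(beta = beta, tmaps = tmaps, dof = dof, sigma2 = sigma2,
                 voxel_index = series$voxel_index),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d voxels, dof %d\n", ncol(x$beta), x$dof))
  invisible(x)
}
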