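# Robust Shared Response Model: X_i ~ W_i R + S_i with orthonormal
# per-subject bases W_i (V x k), a group shared response R (k x T) and
# sparse individual terms S_i, fitted by block-coordinate descent on
#   sum_i ||X_i - W_i R - S_i||_F^2 + gamma sum_i ||S_i||_1 .
# Each block update is an exact minimizer (orthogonal Procrustes for W_i,
# mean back-projection for R, entrywise soft-thresholding for S_i), so
# the objective is non-increasing.

.procrustes <- function(a) {
  # argmin_{W: W'W = I} ||M - W B||_F for a = M B': polar factor of a
  sv <- svd(a)
  sv$u %*% t(sv$v)
}

.soft <- function(x, thr) pmax(x - thr, 0) - pmax(-x - thr, 0)

.as_vxt <- function(x) {
  # accept a bold_series (T x V) or a plain V x T matrix
  if (inherits(x, "bold_series")) t(x$data) else as.matrix(x)
}

#' Fit a robust Shared Response Model to one group
#'
#' @param group_series list of synchronized, in-mask [bold_series()] (or
#'   plain V x T matrices), one per subject; all must share T and V.
#' @param k shared dimension, `k <= min(V, T)`.
#' @param gamma L1 penalty on the individual terms; `gamma = 0` reduces
#'   to the plain (non-robust) SRM. The default `NULL` uses
#'   `0.1 * median(|X|)` over all subjects.
#' @param max_iter,tol stopping rule: relative objective change below
#'   `tol`, at most `max_iter` sweeps.
#' @param seed integer; initialization draws random orthonormal bases
#'   (QR of Gaussian) from this seed.
#' @param w_init optional list of V x k matrices with orthonormal columns
#'   used as the starting bases (overrides the random initialization;
#'   useful for warm starts and reference comparisons).
#' @param group_label `"ALS"` or `"CTL"` (free-form, recorded in the
#'   model).
#' @return an object of class `srm_model`: `k`, `gamma`, `bases` (list of
#'   V x k `W_i`), `shared` (k x T `R`), `individual` (list of V x T
#'   `S_i`), `group_label`, `objective_trace`, `seed`, `subject_ids`.
#' @export
fit_rsrm <- function(group_series, k, gamma = NULL, max_iter = 100L,
                     tol = 1e-6, seed = 1L, group_label = "group",
                     w_init = NULL) {
  xs <- lapply(group_series, .as_vxt)
  n <- length(xs)
  stopifnot(n >= 1L)
  v <- nrow(xs[[1]]); n_t <- ncol(xs[[1]])
  for (x in xs)
    if (nrow(x) != v || ncol(x) != n_t)
      fp_stop("funcphen_shape_mismatch",
              "all subjects must share V and T")
  if (k > min(v, n_t))
    fp_stop("funcphen_k_too_large",
            "k (%d) exceeds min(V, T) = %d", k, min(v, n_t))
  if (all(vapply(xs, function(x) all(x == 0), logical(1))))
    fp_stop("funcphen_degenerate", "all-zero input")
  if (is.null(gamma))
    gamma <- 0.1 * stats::median(abs(unlist(lapply(xs, as.numeric))))
  ids <- names(group_series)
  if (is.null(ids))
    ids <- vapply(seq_len(n), function(i) {
      s <- group_series[[i]]
      if (inherits(s, "bold_series")) s$subject_id else sprintf("s%02d", i)
    }, character(1))

  w <- if (!is.null(w_init)) {
    stopifnot(length(w_init) == n)
    lapply(w_init, as.matrix)
  } else {
    with_seed(split_seed(seed, paste0("rsrm_init/", group_label)), {
      lapply(seq_len(n), function(i)
        qr.Q(qr(matrix(stats::rnorm(v * k), v, k))))
    })
  }
  s <- lapply(seq_len(n), function(i) matrix(0, v, n_t))
  r <- Reduce(`+`, Map(function(wi, xi, si) crossprod(wi, xi - si),
                       w, xs, s)) / n

  objective0 <- 0
  for (i in seq_len(n))
    objective0 <- objective0 + sum((xs[[i]] - w[[i]] %*% r)^2)
  trace <- objective0
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n))
      w[[i]] <- .procrustes((xs[[i]] - s[[i]]) %*% t(r))
    r <- Reduce(`+`, Map(function(wi, xi, si) crossprod(wi, xi - si),
                         w, xs, s)) / n
    obj <- 0
    for (i in seq_len(n)) {
      e <- xs[[i]] - w[[i]] %*% r
      if (gamma > 0) {
        s[[i]] <- .soft(e, gamma / 2)
        obj <- obj + sum((e - s[[i]])^2) + gamma * sum(abs(s[[i]]))
      } else {
        obj <- obj + sum(e^2)
      }
    }
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - obj) <= tol * max(abs(prev), .Machine$double.eps))
      break
  }
  names(w) <- names(s) <- ids
  structure(list(k = as.integer(k), gamma = gamma, bases = w, shared = r,
                 individual = s, group_label = group_label,
                 objective_trace = trace, seed = seed, subject_ids = ids),
            class = "srm_model")
}

#' @export
print.srm_model <- function(x, ...) {
  cat(sprintf("<srm_model> '%s': %d subjects, k = %d, gamma = %.4g, %d sweeps\n",
              x$group_label, length(x$bases), x$k, x$gamma,
              length(x$objective_trace) - 1L))
  invisible(x)
}

#' Transfer a frozen shared response to a new subject
#'
#' Learns an orthonormal basis for a held-out subject against the model's
#' frozen shared response: an initial orthogonal Procrustes solution, one
#' soft-threshold pass for the subject's individual term, then a final
#' Procrustes solve on the individual-corrected data.
#'
#' @param model an [fit_rsrm()] model.
#' @param new_run1 the held-out subject's training run (a [bold_series()]
#'   or V x T matrix); T must equal the model's shared-response length.
#' @return a V x k matrix with orthonormal columns.
#' @export
transfer_basis <- function(model, new_run1) {
  x <- .as_vxt(new_run1)
  r <- model$shared
  if (ncol(x) != ncol(r))
    fp_stop("funcphen_shape_mismatch",
            "run has %d time points but the model's shared response has %d",
            ncol(x), ncol(r))
  w <- .procrustes(x %*% t(r))
  s <- .soft(x - w %*% r, model$gamma / 2)
  .procrustes((x - s) %*% t(r))
}

#' Project a run into a shared space
#'
#' Returns `t(W) X` (k x T): the run expressed in the shared temporal
#' space; any individual term is deliberately discarded so only shared
#' group-specific features remain.
#'
#' @param basis V x k matrix with orthonormal columns (from
#'   [transfer_basis()] or a model's `bases`).
#' @param run a [bold_series()] or V x T matrix.
#' @return k x T numeric matrix.
#' @export
project_shared <- function(basis, run) {
  x <- .as_vxt(run)
  basis <- as.matrix(basis)
  if (nrow(basis) != nrow(x))
    fp_stop("funcphen_shape_mismatch",
            "basis has %d voxels but the run has %d", nrow(basis), nrow(x))
  if (max(abs(crossprod(basis) - diag(ncol(basis)))) > 1e-6)
    fp_stop("funcphen_not_orthonormal", "basis columns are not orthonormal")
  crossprod(basis, x)
}

#' Dual-space features for classification
#'
#' Projects a subject's test run through both the patient-trained and the
#' control-trained shared spaces (basis learned from the training run
#' against each frozen model) and concatenates the two flattened k x T2
#' projections, patient space first. Within each projection the k shared
#' components of frame 1 come first, then frame 2, and so on.
#'
#' @param model_als,model_ctl [fit_rsrm()] models with equal `k`.
#' @param subject_run1 training run of the subject (basis estimation).
#' @param subject_run2 test run of the subject (projection).
#' @return numeric vector of length `2 k T2`.
#' @export
dual_space_features <- function(model_als, model_ctl, subject_run1,
                                subject_run2) {
  if (model_als$k != model_ctl$k)
    fp_stop("funcphen_shape_mismatch", "models disagree on k")
  w_a <- transfer_basis(model_als, subject_run1)
  w_c <- transfer_basis(model_ctl, subject_run1)
  p_a <- project_shared(w_a, subject_run2)
  p_c <- project_shared(w_c, subject_run2)
  c(as.numeric(p_a), as.numeric(p_c))
}
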