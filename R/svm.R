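# Linear maximum-margin classifier (soft-margin SVM, hinge loss,
# L2 regularization), solved in the dual by coordinate descent — the
# LIBLINEAR L1-loss dual algorithm. With tens of training subjects the
# dual has one variable per sample and converges in a handful of sweeps.
# The bias is absorbed as an augmented constant feature (regularized).

#' Train a linear SVM
#'
#' @param x n x p feature matrix.
#' @param y labels, a factor or character/numeric vector with exactly two
#'   levels; the first sorted level is coded -1, the second +1.
#' @param C soft-margin cost (default 1).
#' @param class_weight `"balanced"` (default) scales each sample's cost
#'   by `n / (2 n_class)`, so leave-one-subject-out folds — whose
#'   training sets are necessarily imbalanced against the held-out label
#'   — are not biased toward the majority class; `"none"` uses a uniform
#'   cost.
#' @param max_sweeps,tol dual coordinate-descent controls.
#' @return an object of class `linear_svm` with `w`, `b`, `levels`.
#' @export
linear_svm <- function(x, y, C = 1, class_weight = c("balanced", "none"),
                       max_sweeps = 1000L, tol = 1e-6) {
  class_weight <- match.arg(class_weight)
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L)
    fp_stop("funcphen_bad_labels", "need exactly 2 classes, got %d",
            length(lev))
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  xa <- cbind(x, 1)                      # augmented bias feature
  n <- nrow(xa)
  ci <- rep(C, n)
  if (class_weight == "balanced") {
    n_pos <- sum(yy > 0)
    ci <- C * n / (2 * ifelse(yy > 0, n_pos, n - n_pos))
  }
  q_diag <- rowSums(xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(xa))
  for (sweep in seq_len(max_sweeps)) {
    max_pg <- 0
    for (i in seq_len(n)) {
      g <- yy[i] * sum(w * xa[i, ]) - 1
      pg <- if (alpha[i] <= 0) min(g, 0) else
        if (alpha[i] >= ci[i]) max(g, 0) else g
      max_pg <- max(max_pg, abs(pg))
      if (abs(pg) > 1e-12) {
        a_new <- min(max(alpha[i] - g / q_diag[i], 0), ci[i])
        w <- w + (a_new - alpha[i]) * yy[i] * xa[i, ]
        alpha[i] <- a_new
      }
    }
    if (max_pg < tol) break
  }
  structure(list(w = w[-length(w)], b = w[length(w)], levels = lev,
                 alpha = alpha, C = C),
            class = "linear_svm")
}

#' @rdname linear_svm
#' @param object a `linear_svm` model.
#' @param newdata matrix of rows to classify.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w + object$b
  object$levels[1L + as.integer(score >= 0)]
}
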