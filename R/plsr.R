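# NIPALS partial least squares regression. The decomposition is
#   X_c = T P' + F_X ,  Y_c = U Q' + F_Y ,  U ~ T D ,
# with each component's weight pair (w, c) maximizing cov(Xw, Yc); the
# first weight vector equals the dominant left singular vector of
# X_c' Y_c. X is deflated per component; Y is deflated through the
# fitted regression, so the coefficient matrix is B = W (P' W)^{-1} C'.

#' Fit a PLSR model by NIPALS
#'
#' @param x n x p predictor matrix.
#' @param y n x q response matrix (a vector is treated as q = 1).
#' @param L number of latent components, `L <= min(n - 1, p)`.
#' @param standardize if `TRUE`, scale predictor columns to unit SD
#'   (columns are always mean-centered; scaling is off by default).
#' @param tol,max_iter inner NIPALS iteration controls (q > 1 only).
#' @return an object of class `plsr_model` with `L`, `x_mean`, `y_mean`,
#'   `x_scale`, `T_scores`, `U_scores`, `P_load`, `Q_load`, `W_weights`,
#'   `C_weights`, `D_inner` (L x L diagonal), `coef` (p x q).
#' @export
fit_plsr <- function(x, y, L = 2L, standardize = FALSE, tol = 1e-12,
                     max_iter = 500L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (nrow(y) != n)
    fp_stop("funcphen_shape_mismatch", "x and y row counts differ")
  if (n < 2L)
    fp_stop("funcphen_too_few_subjects", "need n >= 2")
  if (L > min(n - 1L, p))
    fp_stop("funcphen_k_too_large",
            "L (%d) exceeds min(n - 1, p) = %d", L, min(n - 1L, p))
  if (any(apply(y, 2L, stats::sd) == 0))
    fp_stop("funcphen_zero_variance", "a response column has zero variance")
  x_mean <- colMeans(x)
  y_mean <- colMeans(y)
  e <- sweep(x, 2L, x_mean)
  x_scale <- rep(1, p)
  if (standardize) {
    x_scale <- apply(e, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1
    e <- sweep(e, 2L, x_scale, "/")
  }
  f <- sweep(y, 2L, y_mean)

  tt <- uu <- matrix(0, n, L)
  ww <- pp <- matrix(0, p, L)
  cc <- qq <- matrix(0, q, L)
  d <- numeric(L)
  for (l in seq_len(L)) {
    u <- f[, which.max(apply(f, 2L, stats::var)), drop = TRUE]
    w <- t_scores <- NULL
    for (it in seq_len(max_iter)) {
      w <- as.numeric(crossprod(e, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0)
        fp_stop("funcphen_degenerate", "component %d collapsed to zero", l)
      w <- w / nw
      t_scores <- as.numeric(e %*% w)
      c_w <- as.numeric(crossprod(f, t_scores)) / sum(t_scores^2)
      u_new <- as.numeric(f %*% c_w) / sum(c_w^2)
      if (q == 1L || sqrt(sum((u_new - u)^2)) <=
          tol * max(sqrt(sum(u_new^2)), .Machine$double.eps)) {
        u <- u_new
        break
      }
      u <- u_new
      if (it == max_iter)
        fp_stop("funcphen_no_convergence",
                "inner NIPALS loop did not converge for component %d", l)
    }
    t2 <- sum(t_scores^2)
    p_load <- as.numeric(crossprod(e, t_scores)) / t2
    c_w <- as.numeric(crossprod(f, t_scores)) / t2
    q_load <- {
      u2 <- sum(u^2)
      if (u2 > 0) as.numeric(crossprod(f, u)) / u2 else c_w
    }
    d[l] <- sum(u * t_scores) / t2
    e <- e - tcrossprod(t_scores, p_load)
    f <- f - tcrossprod(t_scores, c_w)
    tt[, l] <- t_scores; uu[, l] <- u
    ww[, l] <- w; pp[, l] <- p_load
    cc[, l] <- c_w; qq[, l] <- q_load
  }
  rot <- ww %*% solve(crossprod(pp, ww))    # X_c rot = T
  coef <- rot %*% t(cc)
  structure(list(L = as.integer(L), x_mean = x_mean, y_mean = y_mean,
                 x_scale = x_scale, T_scores = tt, U_scores = uu,
                 P_load = pp, Q_load = qq, W_weights = ww, C_weights = cc,
                 D_inner = diag(d, nrow = L), coef = coef, rotation = rot),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s), p = %d, q = %d\n",
              x$L, nrow(x$coef), ncol(x$coef)))
  invisible(x)
}

#' Predict responses / latent scores from a PLSR model
#'
#' `predict()` returns `(x - x_mean) B + y_mean`; `plsr_latent()` returns
#' the latent coordinates `(x - x_mean) W (P'W)^{-1}`.
#'
#' @param object a [fit_plsr()] model.
#' @param newdata matrix (or vector) of predictor rows.
#' @param ... unused.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  xc <- .plsr_center(object, newdata)
  sweep(xc %*% object$coef, 2L, object$y_mean, "+")
}

#' @rdname predict.plsr_model
#' @param model a [fit_plsr()] model.
#' @export
plsr_latent <- function(model, newdata) {
  .plsr_center(model, newdata) %*% model$rotation
}

.plsr_center <- function(model, newdata) {
  xm <- if (is.null(dim(newdata)))
    matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(xm) != length(model$x_mean))
    fp_stop("funcphen_shape_mismatch", "newdata has wrong column count")
  xc <- sweep(xm, 2L, model$x_mean)
  sweep(xc, 2L, model$x_scale, "/")
}

#' Leave-one-out cross-validation of a PLSR model
#'
#' Per fold: fit on the n - 1 remaining subjects, predict the held-out
#' subject; `mse` is the squared prediction error averaged over response
#' dimensions (with a single response it is the squared error), and
#' `lv1` / `lv2` are the held-out subject's first two latent coordinates
#' in that fold's model.
#'
#' @param x,y as in [fit_plsr()]; `n >= 3`.
#' @param L components per fold model.
#' @param standardize passed to [fit_plsr()].
#' @return `data.frame` with one row per fold: `fold`, `mse`, `lv1`,
#'   `lv2` (`NA` if `L < 2`).
#' @export
loo_cv <- function(x, y, L = 2L, standardize = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3L)
    fp_stop("funcphen_too_few_subjects", "LOO CV needs n >= 3")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- fit_plsr(x[-i, , drop = FALSE], y[-i, , drop = FALSE], L = L,
                    standardize = standardize)
    pred <- predict(fit, x[i, , drop = FALSE])
    lat <- plsr_latent(fit, x[i, , drop = FALSE])
    out[[i]] <- data.frame(fold = i,
                           mse = mean((pred - y[i, ])^2),
                           lv1 = lat[1, 1],
                           lv2 = if (L >= 2L) lat[1, 2] else NA_real_)
  }
  do.call(rbind, out)
}

#' Back-project PLSR weights into voxel space
#'
#' @param model a [fit_plsr()] model whose p predictor columns are the
#'   voxels of `mask` (in mask order).
#' @param mask an [roi_mask()] with `mask_size(mask) == p`.
#' @param what `"w1"` for the first-component weight vector (default) or
#'   `"coef"` for the L-component regression coefficients (first
#'   response).
#' @return a [scalar_map()] aligned with the mask.
#' @export
backproject_weights <- function(model, mask, what = c("w1", "coef")) {
  what <- match.arg(what)
  p <- nrow(model$W_weights)
  if (p != mask_size(mask))
    fp_stop("funcphen_shape_mismatch",
            "model has %d predictors but mask has %d voxels",
            p, mask_size(mask))
  vals <- if (what == "w1") model$W_weights[, 1] else model$coef[, 1]
  scalar_map(vals, mask$voxel_index, paste0("plsr_", what))
}

#' Region-wise weight statistics
#'
#' One observation per subject(-fold) per region: the mean |weight|
#' within the region. A one-way repeated-measures ANOVA with region as
#' the within-subject factor (F = MS_region / MS_region-x-subject,
#' dof (r - 1, (r - 1)(n - 1))) is followed by all pairwise paired
#' t-tests with Holm step-down adjustment.
#'
#' @param weight_maps list of [scalar_map()] (one per subject or fold),
#'   all on the same voxel set.
#' @param rois named list of [roi_mask()] regions (e.g. hand, foot,
#'   tongue), each a subset of the maps' voxels.
#' @return a list: `anova_F`, `dof`, `p`, `region_means` (n x r matrix),
#'   `holm_table` (`data.frame`: `pair`, `t`, `p_raw`, `p_holm`).
#' @export
region_weight_stats <- function(weight_maps, rois) {
  n <- length(weight_maps)
  r <- length(rois)
  if (n < 2L)
    fp_stop("funcphen_too_few_subjects", "need at least 2 maps")
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  map_key <- key(weight_maps[[1]]$voxel_index)
  region_cols <- lapply(rois, function(m) {
    pos <- match(key(m$voxel_index), map_key)
    pos <- pos[!is.na(pos)]
    if (length(pos) == 0L)
      fp_stop("funcphen_empty_mask",
              "region '%s' has no voxels inside the weight maps", m$label)
    pos
  })
  vals <- t(vapply(weight_maps, function(wm)
    vapply(region_cols, function(cols) mean(abs(wm$values[cols])),
           numeric(1)), numeric(r)))
  colnames(vals) <- names(rois)

  gm <- mean(vals)
  ss_region <- n * sum((colMeans(vals) - gm)^2)
  ss_subject <- r * sum((rowMeans(vals) - gm)^2)
  ss_total <- sum((vals - gm)^2)
  ss_err <- ss_total - ss_region - ss_subject
  df1 <- r - 1L
  df2 <- (r - 1L) * (n - 1L)
  ms_region <- ss_region / df1
  ms_err <- ss_err / df2
  f_stat <- if (ms_err > 0) ms_region / ms_err else
    if (ms_region == 0) 0 else Inf
  p_f <- if (is.finite(f_stat)) stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  else 0
  if (f_stat == 0) p_f <- 1

  pairs <- utils::combn(names(rois), 2L)
  raw <- apply(pairs, 2L, function(pr) {
    d <- vals[, pr[1]] - vals[, pr[2]]
    if (stats::sd(d) == 0)
      return(c(t = 0, p = 1))
    tt <- stats::t.test(d)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  holm_table <- data.frame(pair = paste(pairs[1, ], "vs", pairs[2, ]),
                           t = raw["t", ], p_raw = raw["p", ],
                           p_holm = stats::p.adjust(raw["p", ], "holm"))
  rownames(holm_table) <- NULL
  list(anova_F = f_stat, dof = c(df1, df2), p = p_f,
       region_means = vals, holm_table = holm_table)
}

#' Run a full PLSR analysis on a patient cohort
#'
#' Builds the predictor matrix over the combined mask (per patient:
#' eigenvector centrality values, GLM activation t values — per voxel the
#' largest condition t — or the flattened masked time series), regresses
#' the chosen clinical score on it with LOO-validated NIPALS PLSR,
#' back-projects the weights to voxel space per fold, and summarizes
#' region-wise weight statistics for hand, foot and tongue fields.
#'
#' @param bold named list of [bold_series()] for the patients (whole-grid
#'   or combined-mask data).
#' @param records clinical `data.frame` aligned with `names(bold)` via
#'   `patient_id`.
#' @param predictor `"ecm"`, `"activation"` or `"timeseries"`.
#' @param response `"alsfrs"` or `"pumns"`.
#' @param mask combined [roi_mask()] defining the voxels.
#' @param rois named list of [roi_mask()] for the region statistics
#'   (typically hand = LH+RH, foot = LF+RF, tongue).
#' @param schedules named list of [design_schedule()] per patient
#'   (`predictor = "activation"` only).
#' @param L latent components (default 2).
#' @param standardize passed to [fit_plsr()].
#' @return a list: `folds` (LOO records joined with stage and onset),
#'   `weight_map` (full-fit first-component voxel map), `fold_maps`,
#'   `region_stats`, `model`, `predictor`, `response`.
#' @export
run_plsr_analysis <- function(bold, records,
                              predictor = c("ecm", "activation", "timeseries"),
                              response = c("alsfrs", "pumns"),
                              mask, rois, schedules = NULL, L = 2L,
                              standardize = FALSE) {
  predictor <- match.arg(predictor)
  response <- match.arg(response)
  ids <- records$patient_id
  stopifnot(all(ids %in% names(bold)))
  y <- switch(response, alsfrs = records$alsfrs_total, pumns = records$pumns)
  if (stats::sd(y) == 0)
    fp_stop("funcphen_zero_variance", "response '%s' is constant", response)

  v <- mask_size(mask)
  rows <- lapply(ids, function(id) {
    s <- bold[[id]]
    switch(predictor,
      ecm = ecm(s, mask)$values,
      activation = {
        if (is.null(schedules))
          fp_stop("funcphen_bad_config",
                  "predictor 'activation' needs per-subject schedules")
        g <- fit_glm(mask_bold(s, mask), schedules[[id]])
        do.call(pmax, lapply(g$tmaps, `[[`, "values"))
      },
      timeseries = as.numeric(mask_bold(s, mask)$data))
  })
  x <- do.call(rbind, rows)

  folds <- loo_cv(x, y, L = L, standardize = standardize)
  folds$patient_id <- ids
  folds$kings_stage <- records$kings_stage
  folds$onset_type <- records$onset_type

  # per-voxel weight: for time-series predictors, average |w| over frames
  to_voxel <- function(w) {
    if (predictor == "timeseries")
      colMeans(matrix(abs(w), ncol = v))
    else w
  }
  full <- fit_plsr(x, y, L = L, standardize = standardize)
  weight_map <- scalar_map(to_voxel(full$W_weights[, 1]), mask$voxel_index,
                           paste0("plsr_w1_", predictor))
  fold_maps <- lapply(seq_along(ids), function(i) {
    fit <- fit_plsr(x[-i, , drop = FALSE],
                    matrix(y[-i], ncol = 1L), L = L,
                    standardize = standardize)
    scalar_map(to_voxel(fit$W_weights[, 1]), mask$voxel_index,
               sprintf("fold%02d", i))
  })
  region_stats <- region_weight_stats(fold_maps, rois)
  list(folds = folds, weight_map = weight_map, fold_maps = fold_maps,
       region_stats = region_stats, model = full,
       predictor = predictor, response = response)
}
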