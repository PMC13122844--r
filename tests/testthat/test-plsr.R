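test_that("an exact rank-1 linear relation is fit by one component", {
  set.seed(1)
  x1 <- rnorm(12)
  x <- cbind(x1, 2 * x1, -x1)          # rank-1 predictors
  y <- x %*% c(1, 0.5, 1)
  fit <- fit_plsr(x, y, L = 1)
  expect_lt(norm(predict(fit, x) - y, "F"), 1e-8)
})

test_that("full-rank PLSR equals ordinary least squares", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  y <- matrix(rnorm(20), 10, 2)
  fit <- fit_plsr(x, y, L = 4)
  ols <- cbind(1, x) %*% qr.coef(qr(cbind(1, x)), y)
  expect_equal(predict(fit, x), ols, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the first weight vector is the dominant singular vector", {
  set.seed(3)
  for (rep in 1:4) {
    x <- matrix(rnorm(120), 20, 6)
    y <- matrix(rnorm(40), 20, 2)
    fit <- fit_plsr(x, y, L = 2)
    xc <- scale(x, scale = FALSE)
    yc <- scale(y, scale = FALSE)
    u1 <- svd(crossprod(xc, yc))$u[, 1]
    expect_gte(abs(sum(fit$W_weights[, 1] * u1)), 1 - 1e-8)
    expect_equal(sqrt(colSums(fit$W_weights^2)), c(1, 1), tolerance = 1e-10)
  }
})

test_that("scores are orthogonal and deflation is exact at full rank", {
  set.seed(4)
  x <- matrix(rnorm(36), 9, 4)
  y <- rnorm(9)
  l_max <- min(nrow(x) - 1, ncol(x))
  fit <- fit_plsr(x, y, L = l_max)
  g <- crossprod(fit$T_scores)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8 * max(diag(g)))
  # X_c = T P' reconstruction at full rank
  xc <- scale(x, scale = FALSE)
  expect_lt(norm(xc - tcrossprod(fit$T_scores, fit$P_load), "F"), 1e-8)
})

test_that("fit_plsr validates responses and component counts", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(fit_plsr(x, rep(1, 10), L = 1),
               class = "funcphen_zero_variance")
  expect_error(fit_plsr(x, rnorm(10), L = 4),
               class = "funcphen_k_too_large")
  expect_error(fit_plsr(x[1:3, ], rnorm(4), L = 1),
               class = "funcphen_shape_mismatch")
})

test_that("loo_cv returns one calibrated fold per subject", {
  set.seed(5)
  x <- matrix(rnorm(48), 12, 4)
  y <- x %*% c(1, -2, 0.5, 3)          # noiseless linear response
  cv <- loo_cv(x, y, L = 4)
  expect_equal(nrow(cv), 12L)
  expect_equal(cv$fold, 1:12)
  expect_true(all(cv$mse < 1e-10))
  expect_true(all(is.finite(cv$lv1)) && all(is.finite(cv$lv2)))
  expect_error(loo_cv(x[1:2, ], y[1:2], L = 1),
               class = "funcphen_too_few_subjects")
})

test_that("backprojected weights align with the mask and are equivariant", {
  grid <- volume_grid(c(4, 4, 4))
  idx <- matrix(c(0,0,0, 1,0,0, 2,0,0), ncol = 3, byrow = TRUE)
  mask <- roi_mask("m", idx, grid)
  set.seed(6)
  x <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  fit <- fit_plsr(x, y, L = 2)
  wm <- backproject_weights(fit, mask)
  expect_equal(wm$values, fit$W_weights[, 1])
  expect_equal(wm$voxel_index, mask$voxel_index)
  # permuting predictor columns and mask rows identically leaves the
  # (voxel -> weight) assignment invariant
  perm <- c(3, 1, 2)
  fit_p <- fit_plsr(x[, perm], y, L = 2)
  mask_p <- roi_mask("m", idx[perm, ], grid)
  wm_p <- backproject_weights(fit_p, mask_p)
  pos <- match(vox_key(wm$voxel_index), vox_key(idx[perm, , drop = FALSE]))
  expect_equal(abs(fit_p$W_weights[pos, 1]), abs(wm$values),
               tolerance = 1e-10)
  wrong <- roi_mask("m", idx[1:2, ], grid)
  expect_error(backproject_weights(fit, wrong),
               class = "funcphen_shape_mismatch")
})

test_that("Holm adjustment matches hand step-down enumeration", {
  # raw p = (0.01, 0.04, 0.03): sorted (0.01, 0.03, 0.04) with
  # multipliers (3, 2, 1) -> (0.03, 0.06, 0.04) -> monotone -> (0.03,
  # 0.06, 0.06); mapped back to the input order
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  # and through region_weight_stats' table on data with a known ordering
  set.seed(7)
  idx <- cbind(0:5, 0L, 0L)
  grid <- volume_grid(c(6, 4, 4))
  rois <- list(hand = roi_mask("hand", idx[1:2, ], grid),
               foot = roi_mask("foot", idx[3:4, ], grid),
               tongue = roi_mask("tongue", idx[5:6, ], grid))
  maps <- lapply(1:6, function(i)
    scalar_map(c(rnorm(2, 1), rnorm(2, 3), rnorm(2, 3.2)), idx,
               sprintf("m%d", i)))
  rs <- region_weight_stats(maps, rois)
  raw <- rs$holm_table$p_raw
  expect_equal(rs$holm_table$p_holm, p.adjust(raw, "holm"))
  expect_true(all(rs$holm_table$p_holm >= raw))
})

test_that("repeated-measures ANOVA agrees with the aov() oracle", {
  set.seed(8)
  idx <- cbind(0:5, 0L, 0L)
  grid <- volume_grid(c(6, 4, 4))
  rois <- list(hand = roi_mask("hand", idx[1:2, ], grid),
               foot = roi_mask("foot", idx[3:4, ], grid),
               tongue = roi_mask("tongue", idx[5:6, ], grid))
  maps <- lapply(1:4, function(i)
    scalar_map(rnorm(6, mean = rep(c(1, 2, 1.5), each = 2)), idx,
               sprintf("m%d", i)))
  rs <- region_weight_stats(maps, rois)
  expect_equal(rs$anova_F, oracle_rm_anova_F(rs$region_means),
               tolerance = 1e-8)
  expect_equal(rs$dof, c(2L, 6L))
  # identical region values: F = 0, everything non-significant
  flat <- lapply(1:4, function(i)
    scalar_map(rep(i, 6), idx, sprintf("f%d", i)))
  rs0 <- region_weight_stats(flat, rois)
  expect_equal(rs0$anova_F, 0)
  expect_equal(rs0$p, 1)
  expect_true(all(rs0$holm_table$p_holm == 1))
})

test_that("run_plsr_analysis produces a complete report", {
  cfg <- cohort_config(n_patients = 6, n_controls = 1, n_reps = 1, seed = 9)
  ch <- generate_cohort(cfg)
  masks <- cohort_roi_masks(cfg)
  comb <- combined_mask(masks)
  rois <- list(hand = combined_mask(masks[c("LH", "RH")], "hand"),
               foot = combined_mask(masks[c("LF", "RF")], "foot"),
               tongue = masks$TONGUE)
  filt <- lapply(ch$bold[ch$clinical$patient_id], bandpass)
  rep <- run_plsr_analysis(filt, ch$clinical, predictor = "ecm",
                           response = "alsfrs", mask = comb, rois = rois)
  expect_equal(nrow(rep$folds), 6L)
  expect_equal(ncol(rep$region_stats$region_means), 3L)
  expect_equal(length(rep$weight_map$values), mask_size(comb))
  expect_s3_class(rep$model, "plsr_model")
  # constant response refuses to fit
  flat <- ch$clinical
  flat$alsfrs_total <- 40L
  expect_error(run_plsr_analysis(filt, flat, predictor = "ecm",
                                 response = "alsfrs", mask = comb,
                                 rois = rois),
               class = "funcphen_zero_variance")
})

test_that("time-series predictors collapse to voxel weight maps", {
  cfg <- cohort_config(n_patients = 5, n_controls = 1, n_reps = 1, seed = 10)
  ch <- generate_cohort(cfg)
  masks <- cohort_roi_masks(cfg)
  comb <- combined_mask(masks)
  rois <- list(hand = combined_mask(masks[c("LH", "RH")], "hand"),
               foot = combined_mask(masks[c("LF", "RF")], "foot"),
               tongue = masks$TONGUE)
  sync <- Map(synchronize_blocks,
              lapply(ch$bold[ch$clinical$patient_id], bandpass),
              ch$truth$schedules[ch$clinical$patient_id])
  rep <- run_plsr_analysis(sync, ch$clinical, predictor = "timeseries",
                           response = "pumns", mask = comb, rois = rois)
  expect_equal(length(rep$weight_map$values), mask_size(comb))
  expect_true(all(rep$weight_map$values >= 0))   # mean |w| per voxel
})
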