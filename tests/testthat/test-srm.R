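rand_orth <- function(v, k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(v * k), v, k)))
}

test_that("a huge sparsity penalty recovers the plain SRM (S = 0)", {
  set.seed(1)
  xs <- lapply(1:3, function(i) matrix(rnorm(20 * 30), 20, 30))
  gam <- 2 * max(abs(unlist(xs))) * 2
  fit <- fit_rsrm(xs, k = 3, gamma = gam, seed = 2)
  expect_true(all(vapply(fit$individual, function(s) all(s == 0),
                         logical(1))))
})

test_that("one subject with a complete basis is reconstructed exactly", {
  v <- 15; n_t <- 25
  w <- rand_orth(v, 3, 3)
  x <- w %*% matrix(rnorm(3 * n_t), 3, n_t)
  fit <- fit_rsrm(list(x), k = v, gamma = 0, seed = 4, max_iter = 200)
  rel <- norm(x - fit$bases[[1]] %*% fit$shared, "F") / norm(x, "F")
  expect_lt(rel, 1e-6)
})

test_that("the objective is monotone and bases stay orthonormal", {
  set.seed(5)
  for (rep in 1:3) {
    xs <- lapply(1:4, function(i) matrix(rnorm(25 * 30), 25, 30))
    fit <- fit_rsrm(xs, k = 4, seed = rep, max_iter = 40)
    expect_true(all(diff(fit$objective_trace) <= 1e-8 *
                      max(fit$objective_trace)))
    for (w in fit$bases)
      expect_lt(max(abs(crossprod(w) - diag(4))), 1e-6)
  }
})

test_that("gamma = 0 matches an independent alternating-Procrustes SRM", {
  set.seed(6)
  for (rep in 1:5) {
    xs <- lapply(1:3, function(i) matrix(rnorm(30 * 40), 30, 40))
    starts <- lapply(100 + 1:3, function(s) rand_orth(30, 3, s))
    fit <- fit_rsrm(xs, k = 3, gamma = 0, seed = rep, max_iter = 500,
                    tol = 1e-12, w_init = starts)
    mine <- tail(fit$objective_trace, 1)
    oracle <- oracle_plain_srm_objective(xs, k = 3, w_start = starts)
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
})

test_that("fit_rsrm validates shapes and degenerate input", {
  xs <- list(matrix(rnorm(100), 10, 10))
  expect_error(fit_rsrm(xs, k = 11), class = "funcphen_k_too_large")
  expect_error(fit_rsrm(list(matrix(0, 10, 10)), k = 2),
               class = "funcphen_degenerate")
  bad <- list(matrix(rnorm(100), 10, 10), matrix(rnorm(90), 9, 10))
  expect_error(fit_rsrm(bad, k = 2), class = "funcphen_shape_mismatch")
})

test_that("transfer_basis solves the exact Procrustes case", {
  v <- 20; k <- 3; n_t <- 30
  r <- matrix(rnorm(k * n_t), k, n_t)
  w_true <- rand_orth(v, k, 7)
  x <- w_true %*% r
  model <- structure(list(k = k, gamma = 0, shared = r), class = "srm_model")
  w_hat <- transfer_basis(model, x)
  expect_lt(max(abs(crossprod(w_hat) - diag(k))), 1e-6)
  # recovery up to the Procrustes equivalence class: projections agree
  expect_equal(crossprod(w_hat, x), crossprod(w_hat, w_true %*% r),
               tolerance = 1e-8)
  expect_lt(norm(x - w_hat %*% crossprod(w_hat, x), "F") / norm(x, "F"),
            1e-8)
  # pure-noise subject still yields an orthonormal basis
  noise <- matrix(rnorm(v * n_t), v, n_t)
  w_noise <- transfer_basis(model, noise)
  expect_lt(max(abs(crossprod(w_noise) - diag(k))), 1e-6)
  expect_error(transfer_basis(model, noise[, 1:10]),
               class = "funcphen_shape_mismatch")
})

test_that("transferring a training subject is self-consistent", {
  cfg <- cohort_config(n_patients = 3, n_controls = 1, n_reps = 1,
                       snr = 1e9, sparsity = 0, act_amplitude = 0,
                       connectivity_gain = 0, severity_gain = 0, seed = 8)
  ch <- generate_cohort(cfg)
  pat <- names(ch$groups)[ch$groups == "ALS"]
  sync <- Map(synchronize_blocks, ch$bold[pat], ch$truth$schedules[pat])
  fit <- fit_rsrm(sync, k = cfg$k_true, gamma = 0, seed = 9, max_iter = 100)
  w_new <- transfer_basis(fit, sync[[1]])
  proj <- project_shared(w_new, sync[[1]])
  expect_gte(cor(as.numeric(proj), as.numeric(fit$shared)), 0.99)
})

test_that("project_shared is faithful on orthonormal bases", {
  v <- 12; k <- 12
  x <- matrix(rnorm(v * 20), v, 20)
  expect_equal(project_shared(diag(v), x), x)
  w <- rand_orth(v, 4, 10)
  z <- matrix(rnorm(4 * 20), 4, 20)
  expect_equal(project_shared(w, w %*% z), z, tolerance = 1e-10)
  expect_lte(norm(project_shared(w, x), "F"), norm(x, "F") + 1e-10)
  expect_error(project_shared(w * 2, x), class = "funcphen_not_orthonormal")
  expect_error(project_shared(w, x[1:5, ]), class = "funcphen_shape_mismatch")
})

test_that("dual-space features have the documented layout", {
  set.seed(11)
  xs <- lapply(1:3, function(i) matrix(rnorm(15 * 10), 15, 10))
  m1 <- fit_rsrm(xs, k = 2, seed = 1)
  run1 <- matrix(rnorm(15 * 10), 15, 10)
  run2 <- matrix(rnorm(15 * 5), 15, 5)
  f <- dual_space_features(m1, m1, run1, run2)
  expect_length(f, 2 * 2 * 5)
  # identical models give identical halves
  expect_equal(f[1:10], f[11:20])
  # first half is the column-major ALS-space projection
  w <- transfer_basis(m1, run1)
  expect_equal(f[1:10], as.numeric(project_shared(w, run2)))
})

test_that("rSRM recovers generative shared signals on model-class cohorts", {
  # 3-seed version of the 20-seed acceptance property
  for (seed in 1:3) {
    cfg <- cohort_config(n_patients = 4, n_controls = 2, n_reps = 1,
                         snr = 10, act_amplitude = 0, connectivity_gain = 0,
                         severity_gain = 0, seed = seed)
    ch <- generate_cohort(cfg)
    pat <- names(ch$groups)[ch$groups == "ALS"]
    sync <- Map(synchronize_blocks, ch$bold[pat], ch$truth$schedules[pat])
    fit <- fit_rsrm(sync, k = cfg$k_true, seed = 20 + seed, max_iter = 100)
    for (id in pat) {
      r <- cor(as.numeric(fit$bases[[id]] %*% fit$shared),
               as.numeric(ch$truth$basis[[id]] %*% ch$truth$shared$ALS))
      expect_gte(r, 0.95)
    }
  }
})
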