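make_series <- function(cols, tr_s = 2) {
  n_v <- ncol(cols)
  grid <- volume_grid(c(max(4, n_v), 4, 4))
  idx <- cbind(seq_len(n_v) - 1L, 0L, 0L)
  bold_series("s", cols, idx, tr_s, grid)
}

test_that("bandpass rejects DC and keeps/stops the right frequencies", {
  n <- 300; tr <- 2; t <- (0:(n - 1)) * tr
  x <- cbind(dc = rep(5, n),
             inband = sin(2 * pi * 0.05 * t),
             outband = sin(2 * pi * 0.2 * t))
  y <- bandpass(make_series(x))$data
  expect_lt(max(abs(y[, 1])), 1e-6 * 5)
  # FFT amplitude-ratio oracles on the interior (edge effects excluded)
  sl <- 51:250
  gain_in <- fft_amp(y[sl, 2], 0.05, tr) / fft_amp(x[sl, 2], 0.05, tr)
  expect_gte(gain_in, 0.9)
  gain_out <- fft_amp(y[sl, 3], 0.2, tr) / fft_amp(x[sl, 3], 0.2, tr)
  expect_lte(20 * log10(gain_out), -20)
})

test_that("bandpass is linear and preserves metadata", {
  set.seed(3)
  a <- matrix(rnorm(200), 100, 2)
  b <- matrix(rnorm(200), 100, 2)
  s_ab <- bandpass(make_series(2 * a + 3 * b))
  s_a <- bandpass(make_series(a)); s_b <- bandpass(make_series(b))
  expect_equal(s_ab$data, 2 * s_a$data + 3 * s_b$data, tolerance = 1e-8)
  src <- make_series(a)
  out <- bandpass(src)
  expect_identical(out$voxel_index, src$voxel_index)
  expect_identical(out$grid, src$grid)
  expect_identical(out$tr_s, src$tr_s)
})

test_that("bandpass validates band edges and series length", {
  s <- make_series(matrix(rnorm(400), 200, 2))
  expect_error(bandpass(s, 0.1, 0.3), class = "funcphen_bad_band")  # > Nyquist
  expect_error(bandpass(s, 0.05, 0.01), class = "funcphen_bad_band")
  short <- make_series(matrix(rnorm(40), 20, 2))
  expect_error(bandpass(short), class = "funcphen_series_too_short")
})

test_that("zscore_voxels standardizes, zeroes constants, and is idempotent", {
  set.seed(4)
  x <- cbind(rnorm(60, 5, 3), rnorm(60), rep(2, 60))
  expect_warning(z <- zscore_voxels(make_series(x)),
                 class = "funcphen_constant_column")
  expect_equal(colMeans(z$data), c(0, 0, 0), tolerance = 1e-10)
  pop_sd <- sqrt(colMeans(sweep(z$data, 2, colMeans(z$data))^2))
  expect_equal(pop_sd[1:2], c(1, 1), tolerance = 1e-10)
  expect_equal(z$data[, 3], rep(0, 60))
  z2 <- suppressWarnings(zscore_voxels(z))
  expect_equal(z2$data, z$data, tolerance = 1e-10)
})

test_that("synchronize_blocks aligns randomized orders across subjects", {
  cfg <- cohort_config(n_reps = 2)
  sch1 <- generate_design(cfg, seed = 1)
  sch2 <- generate_design(cfg, seed = 2)
  expect_false(identical(sch1$events$condition, sch2$events$condition))
  n_t <- floor(sch1$total_duration_s / 2)
  set.seed(5)
  s1 <- make_series(matrix(rnorm(n_t * 2), n_t, 2))
  s2 <- make_series(matrix(rnorm(n_t * 2), n_t, 2))
  y1 <- synchronize_blocks(s1, sch1)
  y2 <- synchronize_blocks(s2, sch2)
  expect_identical(attr(y1, "frame_labels"), attr(y2, "frame_labels"))
  # total length preserved, re-ordering is a permutation
  expect_equal(nrow(y1$data), n_t)
  expect_equal(sort(attr(y1, "frame_order")), seq_len(n_t))
  # the canonical condition order appears in block order
  lab <- attr(y1, "frame_labels")
  runs <- rle(lab[lab != "rest"])$values
  expect_equal(unique(runs), c("LH", "RH", "LF", "RF", "TONGUE"))
})

test_that("an already-canonical schedule synchronizes to the identity", {
  ev <- data.frame(condition = rep(c("LH","RH","LF","RF","TONGUE"), each = 1),
                   onset_s = 15 + (0:4) * 27, duration_s = 12)
  sch <- design_schedule(ev, 15 + 5 * 27)
  # TR of 1 s divides the 27 s cycle, so every block window has the same
  # frame count and the canonical re-ordering is the identity
  n_t <- sch$total_duration_s
  s <- make_series(matrix(rnorm(n_t * 2), n_t, 2), tr_s = 1)
  y <- synchronize_blocks(s, sch)
  expect_equal(attr(y, "frame_order"), seq_len(n_t))
  expect_equal(y$data, s$data)
  short <- make_series(matrix(rnorm(20 * 2), 20, 2))
  expect_error(synchronize_blocks(short, sch),
               class = "funcphen_schedule_mismatch")
})

test_that("split_runs follows the floor convention and inverts", {
  s10 <- make_series(matrix(rnorm(20), 10, 2))
  r <- split_runs(s10)
  expect_equal(nrow(r$run1$data), 5); expect_equal(nrow(r$run2$data), 5)
  s11 <- make_series(matrix(rnorm(22), 11, 2))
  r11 <- split_runs(s11)
  expect_equal(nrow(r11$run1$data), 5); expect_equal(nrow(r11$run2$data), 6)
  expect_equal(rbind(r11$run1$data, r11$run2$data), s11$data)
  expect_error(split_runs(make_series(matrix(rnorm(6), 3, 2))),
               class = "funcphen_series_too_short")
})

test_that("per cent signal change matches the closed form on a boxcar", {
  cfg <- cohort_config(n_reps = 1)
  sch <- generate_design(cfg, seed = 6)
  n_t <- floor(sch$total_duration_s / 2)
  lab <- frame_labels(sch, n_t, 2)
  base <- matrix(100, n_t, 2)
  task <- base + (lab != "rest")            # +1 amplitude on baseline 100
  region <- roi_mask("r", cbind(0:1, 0L, 0L), volume_grid(c(4, 4, 4)))
  s_task <- make_series(task)
  expect_equal(percent_signal_change(s_task, sch, region), 1,
               tolerance = 1e-9)
  expect_equal(percent_signal_change(make_series(base), sch, region), 0)
  # antisymmetry under flipping the sign of the task modulation
  flipped <- base - (lab != "rest")
  expect_equal(percent_signal_change(make_series(flipped), sch, region), -1,
               tolerance = 1e-9)
  # with a filtered numerator the estimate stays near +1 %
  filt <- bandpass(s_task)
  psc_f <- percent_signal_change(filt, sch, region, raw = s_task)
  expect_gt(psc_f, 0.5); expect_lt(psc_f, 1.5)
  zero <- make_series(matrix(0, n_t, 2))
  expect_error(percent_signal_change(zero, sch, region),
               class = "funcphen_zero_baseline")
})
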