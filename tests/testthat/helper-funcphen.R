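# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written along different code paths than the implementation
# they check.

vox_key <- function(m) paste(m[, 1], m[, 2], m[, 3])

tiny_grid <- function(shape = c(4, 4, 4)) volume_grid(shape)

# a small bold_series with random data on the first n voxels of a grid
toy_series <- function(n_t = 50, n_v = 4, seed = 1, shape = c(4, 4, 4),
                       tr_s = 2) {
  set.seed(seed)
  grid <- volume_grid(shape)
  idx <- lex_order_voxels(as.matrix(expand.grid(
    0:(shape[1] - 1), 0:(shape[2] - 1), 0:(shape[3] - 1))))[seq_len(n_v), ,
                                                            drop = FALSE]
  bold_series(paste0("toy", seed), matrix(rnorm(n_t * n_v), n_t, n_v),
              idx, tr_s, grid)
}

# compact ROI layout on a 20 x 10 x 1 grid: five 3x3x1 clusters, V = 200;
# used for classification-scale cohorts
flat_layout <- function() {
  block <- as.matrix(expand.grid(0:2, 0:2, 0))
  out <- lapply(0:4, function(i) {
    b <- block
    b[, 1] <- b[, 1] + i * 4L
    unname(b)
  })
  names(out) <- c("LH", "RH", "LF", "RF", "TONGUE")
  out
}

classification_cohort <- function(seed = 42, n_per_group = 6, snr = 2) {
  cfg <- cohort_config(n_patients = n_per_group, n_controls = n_per_group,
                       grid_shape = c(20L, 10L, 1L), roi_layout = flat_layout(),
                       k_true = 5L, snr = snr, n_reps = 2L, seed = seed)
  ch <- generate_cohort(cfg)
  sync <- Map(synchronize_blocks, lapply(ch$bold, bandpass),
              ch$truth$schedules)
  list(cfg = cfg, cohort = ch, sync = sync,
       whole = roi_mask("whole", ch$bold[[1]]$voxel_index,
                        ch$bold[[1]]$grid),
       rois = cohort_roi_masks(cfg))
}

# FFT amplitude at frequency f (Hz) of a series sampled at interval tr
fft_amp <- function(x, f, tr) {
  n <- length(x)
  k <- round(f * n * tr) + 1
  2 * Mod(fft(x))[k] / n
}

# independent flood-fill connected components (stack-based DFS)
oracle_flood_fill <- function(idx, connectivity = 26L) {
  n <- nrow(idx)
  keys <- vox_key(idx)
  lab <- integer(n)
  cur <- 0L
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]
  if (connectivity == 6L) neigh <- neigh[rowSums(abs(neigh)) == 1, ]
  for (start in seq_len(n)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[v] > 0L) next
      lab[v] <- cur
      for (r in seq_len(nrow(neigh))) {
        nb <- idx[v, ] + neigh[r, ]
        j <- match(paste(nb[1], nb[2], nb[3]), keys)
        if (!is.na(j) && lab[j] == 0L) stack <- c(stack, j)
      }
    }
  }
  lab
}

# independent plain SRM (gamma = 0) reference: alternating orthogonal
# Procrustes run to a tight tolerance from a given (or SVD-based) start;
# returns the final objective sum_i ||X_i - W_i R||_F^2. The objective
# is non-convex, so comparisons against fit_rsrm share the start point.
oracle_plain_srm_objective <- function(xs, k, n_iter = 500, w_start = NULL) {
  n <- length(xs)
  ws <- if (is.null(w_start)) lapply(xs, function(x) svd(x, nu = k, nv = 0)$u)
  else w_start
  r <- Reduce(`+`, Map(function(w, x) crossprod(w, x), ws, xs)) / n
  obj <- Inf
  for (it in seq_len(n_iter)) {
    for (i in seq_len(n)) {
      sv <- svd(xs[[i]] %*% t(r))
      ws[[i]] <- sv$u %*% t(sv$v)
    }
    r <- Reduce(`+`, Map(function(w, x) crossprod(w, x), ws, xs)) / n
    new_obj <- sum(vapply(seq_len(n), function(i)
      sum((xs[[i]] - ws[[i]] %*% r)^2), numeric(1)))
    if (is.finite(obj) && abs(obj - new_obj) < 1e-10 * max(obj, 1)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  obj
}

# repeated-measures ANOVA F via aov() with an Error stratum
oracle_rm_anova_F <- function(vals) {
  df <- data.frame(y = as.numeric(vals),
                   subject = factor(rep(seq_len(nrow(vals)), ncol(vals))),
                   region = factor(rep(colnames(vals),
                                       each = nrow(vals))))
  fit <- stats::aov(y ~ region + Error(subject / region), data = df)
  summary(fit)[["Error: subject:region"]][[1]]["region", "F value"]
}
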