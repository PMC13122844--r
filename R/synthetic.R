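#' Configuration of a synthetic fMRI cohort
#'
#' Describes the generative world the analysis assumes: two groups
#' (patients, controls) sharing a block design, group-specific
#' low-dimensional shared temporal responses, subject-specific orthonormal
#' spatial bases, sparse individual terms, somatotopic ROI clusters with
#' condition-locked HRF responses, stage-dependent connectivity modulation
#' with an inverted-U profile across King's stages 1-3, and clinical
#' scores (ALSFRS-R, PUMNS) statistically linked to the connectivity
#' latent.
#'
#' Defaults mirror the emulated study where it states them: 14 patients
#' and 12 controls, TR 2 s, 12 s movement blocks with 15 s rest, 4
#' repetitions of each of 5 conditions, and stage offsets with the
#' (-, +, -) inverted-U signs (defaults -0.10, +0.12, -0.20, of the same
#' order as the printed stage-wise connectivity deltas). Remaining
#' parameters (grid size, SNR, gains) are free choices documented in the
#' methods vignette.
#'
#' @param n_patients,n_controls group sizes.
#' @param grid_shape 3-vector of grid dimensions (voxels).
#' @param roi_layout named list of five disjoint voxel-index matrices
#'   labelled LH, RH, LF, RF, TONGUE; `NULL` for the default layout of
#'   five 3x3x3 blocks.
#' @param k_true generative shared dimension.
#' @param snr signal-to-noise ratio: sd(shared + activation) / sd(noise);
#'   `Inf` for noiseless data.
#' @param stage_connectivity_offsets length-3 numeric, patient-minus-control
#'   connectivity modulation per King's stage.
#' @param clinical_noise_sd Gaussian noise on the clinical latents.
#' @param sparsity expected fraction of nonzero entries in each subject's
#'   individual term.
#' @param s_scale amplitude of individual-term entries.
#' @param act_amplitude amplitude of condition-locked HRF responses.
#' @param baseline additive raw-signal baseline (0 by default — the
#'   generative model is `W_i R_g + S_i + activation + noise`; set e.g.
#'   100 to emulate raw scanner units with a per cent signal change
#'   denominator).
#' @param connectivity_gain amplitude of the common latent mixed into all
#'   ROI voxels (0 disables connectivity structure).
#' @param conn_offset_scale converts correlation-unit stage offsets into
#'   mixing-amplitude modulation (matched empirically, see vignette).
#' @param severity_gain strength of the severity-dependent coupling
#'   redistribution within foot and tongue ROIs (0 disables): each of
#'   those voxels' coupling to the common latent is shifted by
#'   `severity_gain * severity * loading_v` with zero-mean voxel loadings.
#' @param shared_condition_locked if `TRUE` (default) the shared response
#'   lives in canonical condition-locked time — subjects with different
#'   block orders align onto the same R_g only after
#'   [synchronize_blocks()], emulating task-driven shared activity. If
#'   `FALSE`, R_g unfolds in raw acquisition time (generic shared
#'   activity, condition-unrelated); localizer recovery tests use this
#'   world so the activation term is the only condition-locked signal.
#' @param tr_s,block_s,rest_s,n_reps design timing (seconds, repetitions).
#' @param seed master integer seed; all draws flow from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 14L, n_controls = 12L,
                          grid_shape = c(15L, 6L, 3L), roi_layout = NULL,
                          k_true = 5L, snr = 2,
                          stage_connectivity_offsets = c(-0.10, 0.12, -0.20),
                          clinical_noise_sd = 0.1,
                          sparsity = 0.05, s_scale = 0.5,
                          act_amplitude = 1, baseline = 0,
                          connectivity_gain = 0.8, conn_offset_scale = 3,
                          severity_gain = 0.5,
                          shared_condition_locked = TRUE,
                          tr_s = 2, block_s = 12, rest_s = 15, n_reps = 4L,
                          seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(roi_layout)) roi_layout <- default_roi_layout(grid_shape)
  stopifnot(identical(sort(names(roi_layout)), sort(CONDITIONS)))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  all_keys <- unlist(lapply(roi_layout, key))
  if (anyDuplicated(all_keys))
    fp_stop("funcphen_infeasible_config", "ROI clusters must be disjoint")
  n_roi_vox <- length(all_keys)
  if (k_true > n_roi_vox)
    fp_stop("funcphen_infeasible_config",
            "k_true (%d) exceeds total in-ROI voxels (%d)", k_true, n_roi_vox)
  if (snr <= 0)
    fp_stop("funcphen_infeasible_config", "snr must be > 0")
  if (n_patients < 1L || n_controls < 1L)
    fp_stop("funcphen_infeasible_config", "need at least one subject per group")
  offsets <- as.numeric(stage_connectivity_offsets)
  stopifnot(length(offsets) == 3L)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 grid_shape = grid_shape, roi_layout = roi_layout,
                 k_true = as.integer(k_true), snr = snr,
                 stage_connectivity_offsets = offsets,
                 clinical_noise_sd = clinical_noise_sd,
                 sparsity = sparsity, s_scale = s_scale,
                 act_amplitude = act_amplitude, baseline = baseline,
                 connectivity_gain = connectivity_gain,
                 conn_offset_scale = conn_offset_scale,
                 severity_gain = severity_gain,
                 shared_condition_locked = isTRUE(shared_condition_locked),
                 tr_s = tr_s, block_s = block_s, rest_s = rest_s,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default somatotopic ROI layout
#'
#' Five disjoint 3x3x3 voxel blocks (LH, RH, LF, RF, TONGUE) spaced along
#' the first grid axis, a cartoon of the somatotopic body-part fields of
#' the sensorimotor strip.
#'
#' @param grid_shape integer 3-vector; must fit 5 blocks of 3 voxels along
#'   axis 1 and 3 voxels along axes 2-3.
#' @return named list of voxel-index matrices.
#' @export
default_roi_layout <- function(grid_shape = c(15L, 6L, 3L)) {
  if (grid_shape[1] < 15L || grid_shape[2] < 3L || grid_shape[3] < 3L)
    fp_stop("funcphen_infeasible_config",
            "grid too small for the default 5 x (3x3x3) ROI layout")
  block <- as.matrix(expand.grid(i = 0:2, j = 0:2, k = 0:2))
  out <- list()
  for (c_i in seq_along(CONDITIONS)) {
    b <- block
    b[, 1] <- b[, 1] + (c_i - 1L) * 3L
    out[[CONDITIONS[c_i]]] <- lex_order_voxels(unname(b))
  }
  out
}

#' ROI masks of a cohort configuration
#'
#' @param config a [cohort_config()].
#' @return named list of [roi_mask()] objects, one per condition.
#' @export
cohort_roi_masks <- function(config) {
  grid <- volume_grid(config$grid_shape)
  lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond)
    roi_mask(cond, config$roi_layout[[cond]], grid))
}

# Smooth unit-variance signal: moving-average-filtered white noise.
smooth_signal <- function(n_t, width = 5L) {
  x <- stats::rnorm(n_t + width)
  x <- stats::filter(x, rep(1 / width, width), sides = 1)
  x <- as.numeric(x[(width + 1):(width + n_t)])
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic two-group fMRI cohort with ground truth
#'
#' Per subject, the voxel time series is
#' `baseline + t(W_i R_g) + t(S_i) + activation + latent mixing + noise`:
#' `R_g` is the group's shared response (k x T), `W_i` a subject-specific
#' orthonormal spatial basis (V x k), `S_i` a sparse individual term,
#' the activation term places condition-locked HRF-convolved boxcar
#' responses in each condition's ROI cluster, a common smooth latent is
#' mixed into all ROI voxels with a stage-dependent amplitude for patients
#' (the inverted-U connectivity modulation), and a severity latent is
#' mixed into foot and tongue ROIs in proportion to a continuous severity
#' latent that also drives the clinical scores. Noise is Gaussian with
#' sd(shared + activation)/snr. Every draw is governed by `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a list with `bold` (list of [bold_series()], patients first),
#'   `clinical` (a patient `data.frame` in the [read_clinical_table()]
#'   layout plus `group`), `groups` (named character vector, `"ALS"` /
#'   `"CTL"` per subject id) and `truth` (generative quantities: per-group
#'   `shared` R_g, per-subject `basis` W_i and `individual` S_i, the
#'   `connectivity_latent` (severity) per patient, `severity_loadings`
#'   over voxels, mixing amplitudes, per-subject schedules and noise sd).
#' @export
generate_cohort <- function(config = cohort_config()) {
  grid <- volume_grid(config$grid_shape)
  shape <- config$grid_shape
  all_idx <- lex_order_voxels(as.matrix(expand.grid(
    i = 0:(shape[1] - 1), j = 0:(shape[2] - 1), k = 0:(shape[3] - 1))))
  v_total <- nrow(all_idx)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  all_key <- key(all_idx)
  roi_cols <- lapply(config$roi_layout, function(m) match(key(m), all_key))
  in_roi <- sort(unique(unlist(roi_cols)))
  sev_rois <- unlist(roi_cols[c("LF", "RF", "TONGUE")])

  n_t <- floor((config$n_reps * 5L * config$block_s +
                (config$n_reps * 5L + 1L) * config$rest_s) / config$tr_s)
  k <- config$k_true
  seed0 <- config$seed

  # group shared responses; scaled by sqrt(V/k) so that, through an
  # orthonormal basis, the shared component has ~unit per-voxel variance
  # (the task-locked shared response dominates task fMRI variance, and
  # snr is defined relative to it)
  shared <- list()
  for (g in c("ALS", "CTL")) {
    shared[[g]] <- with_seed(split_seed(seed0, paste0("shared/", g)), {
      t(replicate(k, smooth_signal(n_t)))
    })
    if (k == 1L) shared[[g]] <- matrix(shared[[g]], nrow = 1L)
    shared[[g]] <- shared[[g]] * sqrt(v_total / k)
  }

  # patient clinical structure
  n_p <- config$n_patients
  n_c <- config$n_controls
  stages <- with_seed(split_seed(seed0, "stages"), {
    base <- rep(c(1L, 2L, 3L), times = pmax(1L, round(n_p * c(6, 4, 4) / 14)))
    sample(rep_len(base, n_p))
  })
  onsets <- with_seed(split_seed(seed0, "onsets"), {
    base <- rep(c("UL", "LL", "B"), times = pmax(1L, round(n_p * c(8, 3, 3) / 14)))
    sample(rep_len(base, n_p))
  })
  sev <- with_seed(split_seed(seed0, "severity"),
                   (stages - 1) + stats::rnorm(n_p, 0, 0.3))
  alsfrs <- with_seed(split_seed(seed0, "alsfrs"), {
    raw <- 46 - 9 * (sev + stats::rnorm(n_p, 0, config$clinical_noise_sd))
    as.integer(round(pmin(48, pmax(0, raw))))
  })
  pumns <- with_seed(split_seed(seed0, "pumns"), {
    u <- 1.2 * (onsets == "UL") + 0.3 * sev +
      stats::rnorm(n_p, 0, config$clinical_noise_sd)
    as.integer(round(pmin(32, pmax(0, 2 + 10 * u))))
  })

  # zero-mean voxel loadings: severity redistributes coupling within the
  # foot/tongue fields without moving net centrality mass out of the
  # hand fields (some voxels gain hubness, others lose it)
  sev_loadings <- numeric(v_total)
  sev_loadings[sev_rois] <- with_seed(split_seed(seed0, "sev_loadings"), {
    l <- stats::rnorm(length(sev_rois))
    l - mean(l)
  })

  ids <- c(sprintf("P%02d", seq_len(n_p)), sprintf("C%02d", seq_len(n_c)))
  groups <- stats::setNames(rep(c("ALS", "CTL"), c(n_p, n_c)), ids)

  conn_gain <- numeric(n_p + n_c)
  conn_gain[] <- config$connectivity_gain
  conn_gain[seq_len(n_p)] <- config$connectivity_gain *
    (1 + config$conn_offset_scale *
       config$stage_connectivity_offsets[stages])

  bold <- vector("list", n_p + n_c)
  bases <- individual <- schedules <- sync_orders <- vector("list", n_p + n_c)
  names(bold) <- names(bases) <- names(individual) <-
    names(schedules) <- names(sync_orders) <- ids
  noise_sd <- stats::setNames(numeric(n_p + n_c), ids)

  for (s_i in seq_along(ids)) {
    id <- ids[s_i]
    grp <- groups[[id]]
    sched <- generate_design(config, seed = split_seed(seed0, paste0("design/", id)))
    schedules[[id]] <- sched

    w <- with_seed(split_seed(seed0, paste0("basis/", id)), {
      q <- qr.Q(qr(matrix(stats::rnorm(v_total * k), v_total, k)))
      q * rep(sign(q[1, ] + (q[1, ] == 0)), each = v_total)
    })
    bases[[id]] <- w

    s_mat <- with_seed(split_seed(seed0, paste0("individual/", id)), {
      nz <- stats::rbinom(v_total * n_t, 1L, config$sparsity)
      matrix(nz * stats::rnorm(v_total * n_t, 0, config$s_scale), v_total, n_t)
    })
    individual[[id]] <- s_mat

    reg <- condition_regressors(sched, n_t, config$tr_s)
    act <- matrix(0, n_t, v_total)
    for (cond in CONDITIONS)
      act[, roi_cols[[cond]]] <- act[, roi_cols[[cond]]] +
        config$act_amplitude * reg[, cond]

    # the shared response is condition-locked: R_g lives in canonical
    # (synchronized) time and appears in each subject's acquisition order
    # through the inverse of the synchronization permutation, so that
    # synchronize_blocks() re-aligns all subjects onto the same R_g
    so <- sync_frame_order(sched, n_t, config$tr_s)
    shared_tv <- t(w %*% shared[[grp]])      # canonical-time T x V
    if (config$shared_condition_locked) {
      inv <- integer(n_t)
      inv[so$order] <- seq_len(n_t)
      shared_tv <- shared_tv[inv, , drop = FALSE]
    }
    signal <- shared_tv + act
    sync_orders[[id]] <- so$order
    sd_sig <- stats::sd(as.numeric(signal))
    nsd <- if (is.finite(config$snr)) sd_sig / config$snr else 0
    noise_sd[[id]] <- nsd

    lat <- with_seed(split_seed(seed0, paste0("latent/", id)), {
      g <- smooth_signal(n_t)
      eps <- if (nsd > 0)
        matrix(stats::rnorm(n_t * v_total, 0, nsd), n_t, v_total)
      else 0
      list(g = g, eps = eps)
    })

    # every ROI voxel couples to the subject's common latent; in patients
    # the foot/tongue voxels' coupling strengthens with the severity
    # latent (voxel-specific loadings), raising their network centrality
    gain_v <- numeric(v_total)
    gain_v[in_roi] <- conn_gain[s_i]
    if (grp == "ALS" && config$severity_gain > 0)
      gain_v <- gain_v + (config$severity_gain * sev[s_i]) * sev_loadings
    mix <- lat$g %*% t(gain_v)

    data <- config$baseline + signal + t(s_mat) + mix + lat$eps
    bold[[id]] <- bold_series(id, data, all_idx, config$tr_s, grid)
  }

  clinical <- data.frame(patient_id = ids[seq_len(n_p)],
                         age_years = 56, sex = "M",
                         onset_type = onsets,
                         alsfrs_total = alsfrs,
                         kings_stage = stages,
                         pumns = pumns,
                         stringsAsFactors = FALSE)
  clinical$first_affected_rois <- unname(ONSET_ROI_MAP[clinical$onset_type])

  truth <- list(shared = shared, basis = bases, individual = individual,
                connectivity_latent = sev, severity_loadings = sev_loadings,
                conn_gain = conn_gain, stages = stages, onsets = onsets,
                schedules = schedules, sync_orders = sync_orders,
                noise_sd = noise_sd, roi_cols = roi_cols, config = config)
  list(bold = bold, clinical = clinical, groups = groups, truth = truth)
}
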