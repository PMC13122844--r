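#' Band-pass filter a BOLD series
#'
#' Zero-phase (forward-backward) Butterworth band-pass, 0.01-0.1 Hz by
#' default, applied independently to every voxel column. The filter is a
#' 4th-order Butterworth design realized as second-order sections (see
#' [butter_bandpass_sos()]); forward-backward application makes the
#' effective attenuation the square of the single-pass response.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 tr_s)`.
#' @param order Butterworth prototype order.
#' @return a [bold_series()] of the same shape with filtered data.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1, order = 4L) {
  stopifnot(inherits(series, "bold_series"))
  fs <- 1 / series$tr_s
  sos <- butter_bandpass_sos(low_hz, high_hz, fs, order)
  bold_with_data(series, sos_filtfilt(series$data, sos))
}

# column z-scoring with selectable denominator
.zscore_matrix <- function(x, sd_type = c("population", "sample"),
                           warn_constant = TRUE) {
  sd_type <- match.arg(sd_type)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  ss <- colSums(xc^2)
  denom <- if (sd_type == "population") sqrt(ss / nrow(x)) else
    sqrt(ss / (nrow(x) - 1))
  zero <- denom <= 0
  if (any(zero) && warn_constant)
    fp_warn("funcphen_constant_column",
            "%d zero-variance column(s) set to zero", sum(zero))
  denom[zero] <- 1
  out <- sweep(xc, 2L, denom, "/")
  out[, zero] <- 0
  out
}

#' Z-score every voxel time course
#'
#' Each column is standardized to mean 0 and population SD 1.
#' Zero-variance columns are set to zero with a warning.
#'
#' @param series a [bold_series()].
#' @return a [bold_series()] with standardized data.
#' @export
zscore_voxels <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  bold_with_data(series, .zscore_matrix(series$data, "population"))
}

#' Re-order time points into canonical condition-block order
#'
#' Subjects perform the movement blocks in randomized orders; shared
#' response modelling requires all subjects to be synchronized. This
#' re-orders the frames so condition blocks appear in the canonical order
#' LH, RH, LF, RF, TONGUE (repetitions kept in temporal order), each block
#' carrying its movement window plus the rest window that follows it. Any
#' lead-in rest frames before the first block stay in place as a baseline
#' prefix, so total length is preserved and subjects emerge with identical
#' condition-time alignment.
#'
#' @param series a [bold_series()].
#' @param schedule the subject's [design_schedule()]; must cover the
#'   series duration.
#' @return a [bold_series()] with permuted rows; the permutation is in
#'   `attr(, "frame_order")` and the canonical label sequence in
#'   `attr(, "frame_labels")`.
#' @export
synchronize_blocks <- function(series, schedule) {
  stopifnot(inherits(series, "bold_series"),
            inherits(schedule, "design_schedule"))
  n_t <- n_timepoints(series)
  tr <- series$tr_s
  ev <- schedule$events
  last_end <- max(ev$onset_s + ev$duration_s)
  if (n_t * tr < last_end - 1e-9 ||
      n_t * tr > schedule$total_duration_s + tr + 1e-9)
    fp_stop("funcphen_schedule_mismatch",
            "series length (%g s) does not match schedule (%g s)",
            n_t * tr, schedule$total_duration_s)
  so <- sync_frame_order(schedule, n_t, tr)
  out <- series
  out$data <- series$data[so$order, , drop = FALSE]
  attr(out, "frame_order") <- so$order
  attr(out, "frame_labels") <- so$labels
  out
}

#' Canonical frame ordering of a schedule
#'
#' The permutation used by [synchronize_blocks()]: lead-in rest frames
#' first, then each condition's blocks (LH, RH, LF, RF, TONGUE;
#' repetitions in temporal order), each block comprising its movement
#' frames plus the rest frames up to the next block's onset.
#'
#' @param schedule a [design_schedule()].
#' @param n_t number of frames.
#' @param tr_s repetition time (s).
#' @return list with `order` (canonical position -> raw frame index) and
#'   `labels` (condition label per canonical position).
#' @export
sync_frame_order <- function(schedule, n_t, tr_s) {
  times <- (seq_len(n_t) - 1) * tr_s
  ev <- schedule$events
  next_onset <- c(ev$onset_s[-1], Inf)
  prefix <- which(times < ev$onset_s[1] - 1e-9)
  windows <- lapply(seq_len(nrow(ev)), function(r)
    which(times >= ev$onset_s[r] - 1e-9 & times < next_onset[r] - 1e-9))
  # when the block+rest cycle is not a TR multiple, window frame counts
  # alternate with slot parity; truncating every window to the common
  # minimum makes the canonical condition-time alignment identical across
  # subjects, with the leftover late-rest frames collected in a tail
  len <- min(lengths(windows))
  order_idx <- prefix
  labels <- rep("rest", length(prefix))
  tail_idx <- integer(0)
  for (cond in CONDITIONS) {
    for (r in which(ev$condition == cond)) {
      fr <- windows[[r]]
      order_idx <- c(order_idx, fr[seq_len(len)])
      labels <- c(labels, rep(cond, len))
      if (length(fr) > len)
        tail_idx <- c(tail_idx, fr[(len + 1):length(fr)])
    }
  }
  tail_idx <- sort(tail_idx)
  list(order = c(order_idx, tail_idx),
       labels = c(labels, rep("rest", length(tail_idx))))
}

#' Split a series into two runs
#'
#' Run 1 is the first `floor(T/2)` frames, run 2 the remainder (the study
#' treats the first half of the synchronized series as Run 1 and the
#' second half as Run 2).
#'
#' @param series a [bold_series()] with at least 4 time points.
#' @return a list with elements `run1` and `run2`.
#' @export
split_runs <- function(series) {
  n_t <- n_timepoints(series)
  if (n_t < 4L)
    fp_stop("funcphen_series_too_short",
            "need at least 4 time points to split runs (got %d)", n_t)
  h <- n_t %/% 2L
  r1 <- bold_with_data(series, series$data[seq_len(h), , drop = FALSE])
  r2 <- bold_with_data(series, series$data[(h + 1L):n_t, , drop = FALSE])
  list(run1 = r1, run2 = r2)
}

#' Per cent signal change of a region
#'
#' For each movement block: task amplitude is the mean filtered signal in
#' the movement window minus the mean in the flanking rest windows (the
#' 15 s rest immediately before and after the block); the baseline
#' denominator is the mean *raw* (unfiltered) signal in those flanking
#' rest windows — band-passing/z-scoring destroys the raw baseline, so
#' the denominator comes from `raw` (see the methods vignette; set
#' `raw = series` to use a single series throughout).
#'
#' @param series a (typically band-passed) [bold_series()], numerator
#'   signal.
#' @param schedule the subject's [design_schedule()].
#' @param region an [roi_mask()] of the voxels to average.
#' @param raw a [bold_series()] with unstandardized signal for the
#'   baseline denominator; defaults to `series`.
#' @return mean per cent signal change over blocks (a single number).
#' @export
percent_signal_change <- function(series, schedule, region, raw = series) {
  stopifnot(inherits(series, "bold_series"))
  sub_f <- mask_bold(series, region)
  sub_r <- mask_bold(raw, region)
  n_t <- n_timepoints(series)
  tr <- series$tr_s
  times <- (seq_len(n_t) - 1) * tr
  ev <- schedule$events
  next_onset <- c(ev$onset_s[-1], Inf)
  prev_end <- c(-Inf, (ev$onset_s + ev$duration_s)[-nrow(ev)])
  psc <- numeric(nrow(ev))
  for (r in seq_len(nrow(ev))) {
    on <- ev$onset_s[r]; off <- on + ev$duration_s[r]
    task <- times >= on - 1e-9 & times < off - 1e-9
    flank <- (times >= prev_end[r] - 1e-9 & times < on - 1e-9) |
      (times >= off - 1e-9 & times < next_onset[r] - 1e-9)
    if (!any(task) || !any(flank))
      fp_stop("funcphen_schedule_mismatch",
              "block %d has no task or rest frames", r)
    base <- mean(sub_r$data[flank, , drop = FALSE])
    if (abs(base) < 1e-12)
      fp_stop("funcphen_zero_baseline", "rest baseline is zero in block %d", r)
    num <- mean(sub_f$data[task, , drop = FALSE]) -
      mean(sub_f$data[flank, , drop = FALSE])
    psc[r] <- 100 * num / base
  }
  mean(psc)
}
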