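# Peak value of the un-normalized double-gamma, found once on a dense grid.
.hrf_env <- new.env(parent = emptyenv())

.hrf_raw <- function(t) {
  # canonical double-gamma: positive lobe peaking ~5 s, undershoot ~15 s
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Canonical haemodynamic response function
#'
#' Double-gamma HRF (SPM-style shape parameters: response gamma(6, 1),
#' undershoot gamma(16, 1) scaled by 1/6), normalized to unit peak. Used
#' both to synthesize BOLD responses and as the GLM convolution kernel.
#'
#' @param t time in seconds since stimulus onset; must be `>= 0`.
#' @return HRF value(s); `hrf(0) == 0`, peak value 1 near 5 s, with a late
#'   undershoot around 15 s.
#' @export
hrf <- function(t) {
  if (any(t < 0))
    fp_stop("funcphen_bad_hrf_time", "hrf is defined for t >= 0 only")
  if (is.null(.hrf_env$peak)) {
    grid <- seq(0, 32, by = 0.001)
    .hrf_env$peak <- max(.hrf_raw(grid))
  }
  .hrf_raw(t) / .hrf_env$peak
}

#' Convolve a block design into per-condition BOLD regressors
#'
#' Boxcar (one inside movement blocks) convolved with [hrf()] at the scan
#' resolution, one column per condition plus nothing else (the intercept is
#' added by the GLM).
#'
#' @param schedule a [design_schedule()].
#' @param n_t number of frames.
#' @param tr_s repetition time (s).
#' @return `n_t` x 5 numeric matrix with columns LH, RH, LF, RF, TONGUE.
#' @export
condition_regressors <- function(schedule, n_t, tr_s) {
  lab <- frame_labels(schedule, n_t, tr_s)
  kern_t <- seq(0, 32, by = tr_s)
  kern <- hrf(kern_t)
  out <- matrix(0, n_t, length(CONDITIONS),
                dimnames = list(NULL, CONDITIONS))
  for (cond in CONDITIONS) {
    box <- as.numeric(lab == cond)
    conv <- stats::convolve(c(box, rep(0, length(kern))), rev(kern),
                            type = "open")[seq_len(n_t)]
    out[, cond] <- conv
  }
  out
}
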