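#' Block-design schedule
#'
#' A movement block design: events are (condition, onset, duration) with
#' conditions drawn from the five movement conditions LH, RH, LF, RF,
#' TONGUE (left/right hand, left/right foot, tongue/face).
#'
#' @param events `data.frame` with columns `condition`, `onset_s`,
#'   `duration_s`; events must not overlap in time and every condition
#'   must occur at least once.
#' @param total_duration_s total run duration in seconds.
#' @return an object of class `design_schedule`.
#' @export
design_schedule <- function(events, total_duration_s) {
  events <- as.data.frame(events)
  stopifnot(all(c("condition", "onset_s", "duration_s") %in% names(events)))
  if (!all(events$condition %in% CONDITIONS))
    fp_stop("funcphen_bad_design", "unknown condition label")
  if (!all(CONDITIONS %in% events$condition))
    fp_stop("funcphen_bad_design", "every condition must appear at least once")
  if (any(events$onset_s < 0) || any(events$duration_s <= 0))
    fp_stop("funcphen_bad_design", "onsets must be >= 0, durations > 0")
  o <- order(events$onset_s)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  ends <- events$onset_s + events$duration_s
  if (any(ends[-length(ends)] > events$onset_s[-1] + 1e-9))
    fp_stop("funcphen_bad_design", "events overlap in time")
  if (any(ends > total_duration_s + 1e-9))
    fp_stop("funcphen_bad_design", "events exceed total duration")
  structure(list(events = events,
                 total_duration_s = as.numeric(total_duration_s)),
            class = "design_schedule")
}

#' @export
print.design_schedule <- function(x, ...) {
  cat(sprintf("<design_schedule> %d events over %.0f s\n",
              nrow(x$events), x$total_duration_s))
  invisible(x)
}

#' Generate a randomized block-design schedule
#'
#' Builds the study's movement paradigm: each of the 5 conditions repeated
#' `n_reps` times (20 blocks at the default 4), each block `block_s`
#' seconds of movement separated by `rest_s` seconds of rest, in an order
#' randomized under the seed. Rest precedes the first and follows the last
#' block, so a default run lasts 20 x 12 + 21 x 15 = 555 s.
#'
#' @param config a [cohort_config()]; its `block_s`, `rest_s`, `n_reps`
#'   and `seed` fields are used.
#' @param seed optional integer overriding `config$seed`.
#' @return a [design_schedule()].
#' @export
generate_design <- function(config = cohort_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  conds <- rep(CONDITIONS, times = config$n_reps)
  conds <- with_seed(split_seed(seed, "design"), sample(conds))
  n <- length(conds)
  onsets <- config$rest_s + (seq_len(n) - 1) * (config$block_s + config$rest_s)
  total <- n * config$block_s + (n + 1) * config$rest_s
  design_schedule(data.frame(condition = conds, onset_s = onsets,
                             duration_s = config$block_s), total)
}

#' Sample a schedule's condition labels on the scan grid
#'
#' @param schedule a [design_schedule()].
#' @param n_t number of frames.
#' @param tr_s repetition time (s). Frame `i` (1-based) covers
#'   `[(i-1) tr, i tr)` and is labelled by the event active at its start.
#' @return character vector of length `n_t`: a condition label or `"rest"`.
#' @export
frame_labels <- function(schedule, n_t, tr_s) {
  times <- (seq_len(n_t) - 1) * tr_s
  lab <- rep("rest", n_t)
  for (e in seq_len(nrow(schedule$events))) {
    ev <- schedule$events[e, ]
    on <- times >= ev$onset_s - 1e-9 & times < ev$onset_s + ev$duration_s - 1e-9
    lab[on] <- ev$condition
  }
  lab
}
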