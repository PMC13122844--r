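#' @keywords internal
#' @noRd
fp_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "funcphen_error"),
                      call = sys.call(-1)))
}

#' @keywords internal
#' @noRd
fp_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "funcphen_warning"),
                           call = sys.call(-1)))
}
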