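#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Each
#' module draws from its own stream, obtained by hashing the master seed
#' together with a string label (a counter-based splitting scheme), so that
#' stages can be re-run and tested independently without perturbing each
#' other's draws.
#'
#' @param seed integer master seed.
#' @param label character stream label, e.g. `"cohort/shared"`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
split_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647          # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (code in utf8ToInt(label)) {
    # 31-based polynomial rolling hash; doubles stay < 2^53 so %% is exact
    h <- (h * 31 + code) %% m
  }
  h <- (h * 69069 + 1) %% m
  as.integer(h) + 1L
}

#' Evaluate an expression under a local RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
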