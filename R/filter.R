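# Butterworth band-pass design and zero-phase filtering, implemented as
# cascaded second-order sections (SOS). Transfer-function (b, a) forms of
# order 8 are numerically fragile at the very low normalized frequencies
# used in fMRI (0.01 Hz at fs = 0.5 Hz); SOS form is the standard remedy.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Analog Butterworth prototype of order `order`, low-pass-to-band-pass
#' transformed with bilinear prewarping. An order-`n` design therefore has
#' `2n` poles (the scipy `butter(n, ..., "bandpass")` convention); zeros
#' sit at z = +1 and z = -1, so DC is rejected exactly.
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling frequency in Hz.
#' @param order prototype order (default 4).
#' @return a list of sections, each `list(b = c(b0, b1, b2), a = c(a1, a2))`.
#' @keywords internal
#' @export
butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 4L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    fp_stop("funcphen_bad_band",
            "need 0 < low (%.4g) < high (%.4g) < Nyquist (%.4g)",
            low_hz, high_hz, fs / 2)
  n <- as.integer(order)
  stopifnot(n >= 1L)
  # prewarped analog band edges (bilinear transform with Omega = tan(pi f/fs))
  wl <- tan(pi * low_hz / fs)
  wh <- tan(pi * high_hz / fs)
  bw <- wh - wl
  w0sq <- wl * wh

  # prototype poles on the left unit semicircle
  proto <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  # keep one representative per conjugate pair (Im >= 0); real poles once
  proto <- proto[Im(proto) > 1e-12 | abs(Im(proto)) <= 1e-12]
  proto <- proto[Im(proto) >= -1e-12]

  z_pairs <- list()
  real_z <- complex(0)
  for (p in proto) {
    disc <- sqrt((bw * p)^2 - 4 * w0sq + 0i)
    s_pair <- c((bw * p + disc) / 2, (bw * p - disc) / 2)
    z <- (1 + s_pair) / (1 - s_pair)      # bilinear map
    if (abs(Im(p)) <= 1e-12) {
      # real prototype pole: its two band-pass poles are conjugates or
      # both real; either way they form one section together
      z_pairs[[length(z_pairs) + 1L]] <- z
    } else {
      # complex prototype pole: each band-pass pole pairs with the
      # conjugate arising from conj(p)
      for (zz in z) z_pairs[[length(z_pairs) + 1L]] <- c(zz, Conj(zz))
    }
  }

  sos <- lapply(z_pairs, function(zp) {
    a1 <- -Re(zp[1] + zp[2])
    a2 <- Re(zp[1] * zp[2])
    list(b = c(1, 0, -1), a = c(a1, a2))
  })

  # normalize gain to 1 at the band's geometric-centre frequency
  wc <- 2 * atan(sqrt(w0sq))
  z <- exp(1i * wc)
  gain <- 1
  for (s in sos) {
    num <- 1 - z^-2
    den <- 1 + s$a[1] * z^-1 + s$a[2] * z^-2
    gain <- gain * abs(num / den)
  }
  g_sec <- (1 / gain)^(1 / length(sos))
  lapply(sos, function(s) list(b = s$b * g_sec, a = s$a))
}

# steady-state initial conditions of one biquad for a unit step
# (transposed direct-form II; scipy lfilter_zi equivalent)
.biquad_zi <- function(b, a) {
  A <- matrix(c(-a[1], 1, -a[2], 0), 2L, 2L, byrow = TRUE)
  B <- c(b[2] - a[1] * b[1], b[3] - a[2] * b[1])
  solve(diag(2) - A, B)
}

# filter all columns of x through one biquad, initial state matched to the
# first row (removes the step transient for signals starting at a plateau)
.biquad_filter <- function(x, b, a) {
  zi <- .biquad_zi(b, a)
  z1 <- zi[1] * x[1, ]
  z2 <- zi[2] * x[1, ]
  out <- x
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    y <- b[1] * xt + z1
    z1 <- b[2] * xt - a[1] * y + z2
    z2 <- b[3] * xt - a[2] * y
    out[t, ] <- y
  }
  out
}

.sos_filter <- function(x, sos) {
  for (s in sos) x <- .biquad_filter(x, s$b, s$a)
  x
}

#' Zero-phase filtering of matrix columns through second-order sections
#'
#' Forward-backward application with odd-reflection edge padding
#' (scipy `sosfiltfilt` style), so the result has zero phase shift and
#' squared magnitude response.
#'
#' @param x numeric matrix, series in columns.
#' @param sos section list from [butter_bandpass_sos()].
#' @param padlen padding length; default `6 * (2 * nsections + 1)`.
#' @return filtered matrix of the same shape.
#' @keywords internal
#' @export
sos_filtfilt <- function(x, sos, padlen = NULL) {
  x <- as.matrix(x)
  n_t <- nrow(x)
  if (is.null(padlen)) padlen <- 6L * (2L * length(sos) + 1L)
  if (n_t <= padlen + 1L)
    fp_stop("funcphen_series_too_short",
            "need more than %d time points for filter edge padding (got %d)",
            padlen + 1L, n_t)
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[n_t, ], padlen, ncol(x), byrow = TRUE) -
    x[(n_t - 1):(n_t - padlen), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- .sos_filter(xp, sos)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- .sos_filter(y, sos)
  y <- y[nrow(y):1, , drop = FALSE]
  y[(padlen + 1):(padlen + n_t), , drop = FALSE]
}
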