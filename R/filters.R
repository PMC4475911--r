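#' The eight-band LFP filter bank
#'
#' Standard multiband decomposition of motor-cortex field potentials.  The four
#' narrow bands (delta 0.3--2, theta 2--7, alpha 7--15, beta 15--30 Hz)
#' contribute amplitude, analytic-signal and cosine/sine phase features; the
#' four broad bands (gamma1 30--60, gamma2 60--100, mua1 100--200,
#' mua2 200--400 Hz) contribute amplitude and analytic-signal features only,
#' because instantaneous phase is not a meaningful single-oscillation quantity
#' for a multi-octave band.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz` and `kind`
#'   (`"narrow"` or `"broad"`).
#' @export
#' @examples
#' lfp_bands()
lfp_bands <- function() {
  tibble(
    band    = c("delta", "theta", "alpha", "beta",
                "gamma1", "gamma2", "mua1", "mua2"),
    low_hz  = c(0.3, 2, 7, 15, 30, 60, 100, 200),
    high_hz = c(2, 7, 15, 30, 60, 100, 200, 400),
    kind    = c(rep("narrow", 4), rep("broad", 4))
  )
}

#' Causal Butterworth band-pass filter as second-order sections
#'
#' Designs a causal (forward-only) Butterworth band-pass filter from an
#' analog low-pass prototype of the given order via the low-pass-to-band-pass
#' transform and the bilinear transform with frequency pre-warping.  The
#' result is returned as a cascade of biquads rather than a single
#' transfer function: for very low normalized corner frequencies (the
#' 0.3--2 Hz band at 1 kS/s) the expanded polynomial form is numerically
#' unstable in double precision, while the cascade is exact and stable.
#'
#' @param low_hz,high_hz Passband corner frequencies in Hz.
#' @param fs_hz Sampling rate in Hz.
#' @param order Prototype order (poles per skirt); the band-pass filter has
#'   `2 * order` poles.  Default 4.
#' @return An object of class `sos_filter`: a matrix with one row per biquad
#'   (`b0 b1 b2 a0 a1 a2`), with attributes recording the design.
#' @export
#' @examples
#' flt <- design_band_filter(15, 30, 1000)
#' # unit gain at the geometric centre frequency
#' Mod(sos_freqz(flt, sqrt(15 * 30), 1000))
design_band_filter <- function(low_hz, high_hz, fs_hz, order = 4) {
  check_positive(fs_hz, "fs_hz")
  check_positive(order, "order")
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz < 0 ||
      high_hz <= low_hz) {
    abort("need 0 <= low_hz < high_hz")
  }
  if (high_hz >= fs_hz / 2) {
    abort(sprintf("corner %g Hz is at or above Nyquist (%g Hz)",
                  high_hz, fs_hz / 2))
  }
  w1 <- tan(pi * low_hz / fs_hz)
  w2 <- tan(pi * high_hz / fs_hz)
  bw <- w2 - w1
  w0sq <- w1 * w2
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # Re < 0
  poles <- complex(0)
  for (p in proto) {
    disc <- sqrt((bw * p / 2)^2 - w0sq)
    poles <- c(poles, bw * p / 2 + disc, bw * p / 2 - disc)
  }
  zp <- (1 + poles) / (1 - poles)            # bilinear transform
  pos <- zp[Im(zp) > 0]
  pos <- pos[order(Mod(pos))]
  if (length(pos) != order) abort("pole pairing failed; check corner frequencies")
  sos <- matrix(0, order, 6)
  for (j in seq_len(order)) {
    p <- pos[j]
    # band-pass zeros: one at z = +1 (DC), one at z = -1 (Nyquist) per section
    sos[j, ] <- c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }
  if (any(Mod(pos) >= 1)) abort("designed filter is unstable")
  g <- Mod(sos_response(sos, sqrt(low_hz * high_hz), fs_hz))
  sos[, 1:3] <- sos[, 1:3] / g^(1 / order)
  structure(sos,
            class = "sos_filter",
            low_hz = low_hz, high_hz = high_hz,
            fs_hz = fs_hz, order = order)
}

#' Causal Butterworth low-pass filter as second-order sections
#'
#' Companion to [design_band_filter()] for low-pass responses (used e.g. for
#' slowly varying amplitude envelopes).  `order` must be even.
#'
#' @param cutoff_hz Cutoff frequency in Hz.
#' @inheritParams design_band_filter
#' @return An `sos_filter`.
#' @export
design_lowpass_filter <- function(cutoff_hz, fs_hz, order = 4) {
  check_positive(cutoff_hz, "cutoff_hz")
  check_positive(fs_hz, "fs_hz")
  if (order %% 2 != 0) abort("order must be even")
  if (cutoff_hz >= fs_hz / 2) abort("cutoff at or above Nyquist")
  wc <- tan(pi * cutoff_hz / fs_hz)
  k <- seq_len(order)
  poles <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  zp <- (1 + poles) / (1 - poles)
  pos <- zp[Im(zp) > 0]
  pos <- pos[order(Mod(pos))]
  sos <- matrix(0, order / 2, 6)
  for (j in seq_len(order / 2)) {
    p <- pos[j]
    sos[j, ] <- c(1, 2, 1, 1, -2 * Re(p), Mod(p)^2)
  }
  g <- Mod(sos_response(sos, fs_hz * 1e-9, fs_hz)) # DC gain
  sos[, 1:3] <- sos[, 1:3] / g^(1 / nrow(sos))
  structure(sos, class = "sos_filter", low_hz = 0, high_hz = cutoff_hz,
            fs_hz = fs_hz, order = order)
}

sos_response <- function(sos, f_hz, fs_hz) {
  z <- exp(-2i * pi * f_hz / fs_hz)
  h <- rep(1 + 0i, length(f_hz))
  for (j in seq_len(nrow(sos))) {
    h <- h * (sos[j, 1] + sos[j, 2] * z + sos[j, 3] * z^2) /
      (sos[j, 4] + sos[j, 5] * z + sos[j, 6] * z^2)
  }
  h
}

#' Frequency response of a second-order-section filter
#'
#' @param filt An `sos_filter` from [design_band_filter()].
#' @param f_hz Frequencies at which to evaluate the response.
#' @param fs_hz Sampling rate; defaults to the design rate.
#' @return Complex response at each frequency.
#' @export
sos_freqz <- function(filt, f_hz, fs_hz = attr(filt, "fs_hz")) {
  sos_response(unclass(filt), f_hz, fs_hz)
}

#' Apply a second-order-section filter causally
#'
#' Runs the biquad cascade forward over the signal (direct form, zero initial
#' state), so the output at time t depends only on inputs at times <= t.
#'
#' @param filt An `sos_filter`.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
sos_filtfwd <- function(filt, x) {
  sos <- unclass(filt)
  for (j in seq_len(nrow(sos))) {
    x <- signal::filter(sos[j, 1:3], sos[j, 4:6], x)
  }
  as.numeric(x)
}

#' Closed-form Butterworth band-pass magnitude response
#'
#' Analytic magnitude of the digital band-pass designed by
#' [design_band_filter()] (bilinear transform of the analog prototype, hence
#' expressed in pre-warped frequencies).  Used as an independent oracle for
#' the numerical design.
#'
#' @inheritParams design_band_filter
#' @param f_hz Frequencies at which to evaluate.
#' @return Magnitude (gain) at each frequency.
#' @export
butter_bandpass_gain <- function(f_hz, low_hz, high_hz, fs_hz, order = 4) {
  w <- tan(pi * f_hz / fs_hz)
  w1 <- tan(pi * low_hz / fs_hz)
  w2 <- tan(pi * high_hz / fs_hz)
  om <- (w^2 - w1 * w2) / ((w2 - w1) * w)
  1 / sqrt(1 + om^(2 * order))
}

#' Analytic signal via the discrete Hilbert transform
#'
#' Frequency-domain construction over the full block: the FFT is taken, the
#' negative-frequency half is zeroed and the positive half doubled, and the
#' inverse FFT returns the complex analytic signal whose modulus is the
#' amplitude envelope and whose argument is the instantaneous phase.
#'
#' @param x Real signal.
#' @return Complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) abort("signal too short for the Hilbert transform")
  xf <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(xf * h, inverse = TRUE) / n
}
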