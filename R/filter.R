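# Butterworth band-pass conditioning of the PPG.
#
# The filter is designed analytically (analog Butterworth prototype,
# low-pass -> band-pass transformation, bilinear transform) and realized as
# cascaded second-order sections whose numerator zeros sit *exactly* at
# z = +1 and z = -1. A single direct-form transfer function of order 2n is
# numerically ill-conditioned at these narrow normalized cut-offs
# (0.5 Hz at fs = 125 Hz): its rounded coefficients visibly leak DC. The
# biquad cascade annihilates constants to machine precision.

#' Band-pass filter specification
#'
#' Defaults follow standard PPG conditioning: a 4th-order Butterworth
#' band-pass with pass-band 0.5-8 Hz, removing baseline drift (below
#' 0.5 Hz) and powerline interference (far above 8 Hz). `mode` selects
#' zero-phase forward-backward application (default; preserves pulse
#' morphology, which matters because derivative channels are formed later)
#' or single-pass causal filtering.
#'
#' @param order Filter order of the underlying low-pass prototype (the
#'   band-pass has `2 * order` poles, the usual design convention).
#' @param low_hz,high_hz Pass-band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param mode `"zero-phase"` or `"causal"`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, low_hz = 0.5, high_hz = 8,
                        mode = c("zero-phase", "causal")) {
  check_number(order, "order", min = 1)
  check_number(low_hz, "low_hz", min = 0, strict_min = TRUE)
  check_number(high_hz, "high_hz", min = low_hz, strict_min = TRUE)
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, mode = match.arg(mode)),
            class = "filter_spec")
}

#' Butterworth band-pass as second-order sections
#'
#' Analytic zero-pole-gain design bilinear-transformed to the z-plane and
#' paired into biquads. Each section has numerator `(1, 0, -1)` (zeros
#' pinned at z = +1 and z = -1), so DC and Nyquist are rejected exactly;
#' the cascade gain normalizes the response to 1 at the geometric center
#' frequency.
#'
#' @param order Prototype order (band-pass has `2 * order` poles).
#' @param low_hz,high_hz Band edges, Hz.
#' @param fs Sampling rate, Hz.
#' @return A list with `sos` (n x 6 matrix, columns b0 b1 b2 a0 a1 a2) and
#'   `gain` applied to the first section.
#' @export
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  if (high_hz >= fs / 2)
    abort_field("high_hz", "must be below the Nyquist frequency fs/2")
  if (low_hz <= 0) abort_field("low_hz", "must be > 0")
  n <- as.integer(order)
  # Pre-warped analog band edges, center and bandwidth
  wl <- 2 * fs * tan(pi * low_hz / fs)
  wh <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # Analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k - 1 + n) / (2 * n))
  # Low-pass -> band-pass: each prototype pole spawns two analog poles
  bp <- bw * proto / 2
  s_poles <- c(bp + sqrt(bp^2 - w0^2), bp - sqrt(bp^2 - w0^2))
  # Bilinear transform to z-plane
  z_poles <- (1 + s_poles / (2 * fs)) / (1 - s_poles / (2 * fs))
  if (any(Mod(z_poles) >= 1)) stop("unstable design (pole outside unit circle)")

  upper <- z_poles[Im(z_poles) > 1e-12]
  realp <- Re(z_poles[abs(Im(z_poles)) <= 1e-12])
  sections <- lapply(upper, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(realp) > 0) {
    # pair real poles (possible only for odd prototype orders)
    realp <- sort(realp)
    for (i in seq(1, length(realp), by = 2)) {
      sections <- c(sections, list(c(1, -(realp[i] + realp[i + 1]),
                                     realp[i] * realp[i + 1])))
    }
  }
  sos <- t(vapply(sections, function(a) c(1, 0, -1, a), numeric(6)))
  # Normalize to unit gain at the digital image of the analog center w0
  wd <- 2 * atan(w0 / (2 * fs))
  z1 <- exp(1i * wd)
  resp <- prod(vapply(seq_len(nrow(sos)), function(i) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    Mod((b[1] + b[2] / z1 + b[3] / z1^2) / (a[1] + a[2] / z1 + a[3] / z1^2))
  }, numeric(1)))
  list(sos = sos, gain = 1 / resp)
}

sos_filter_causal <- function(sys, x) {
  y <- x * sys$gain
  for (i in seq_len(nrow(sys$sos))) {
    b <- sys$sos[i, 1:3]
    a <- sys$sos[i, 4:6]
    y <- as.numeric(signal::filter(b, a, y))
  }
  y
}

#' Band-pass filter a signal
#'
#' Applies the Butterworth band-pass of `spec` to `x`. In `"zero-phase"`
#' mode the cascade is run forward and backward over an odd-reflection
#' padded copy of the signal (padding long enough to absorb the slow
#' low-edge transient), giving zero phase distortion and doubled stop-band
#' attenuation in dB; `"causal"` mode is a single forward pass.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop("`spec` must be a filter_spec")
  if (spec$high_hz >= fs / 2)
    abort_field("high_hz", "must be below fs/2")
  n <- length(x)
  if (n <= 3 * spec$order)
    stop("signal too short to filter (need length > 3 * order)", call. = FALSE)
  sys <- butter_bandpass_sos(spec$order, spec$low_hz, spec$high_hz, fs)
  if (spec$mode == "causal") return(sos_filter_causal(sys, x))
  pad <- min(n - 1L, max(50L, round(10 * fs / spec$low_hz)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sos_filter_causal(sys, xp)
  y <- rev(sos_filter_causal(sys, rev(y)))
  y[(pad + 1):(pad + n)]
}
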