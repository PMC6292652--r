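# Band-pass filtering and analytic-signal extraction.
#
# No DSP package is assumed: the Butterworth band-pass is designed from the
# analog prototype (poles on the unit circle), transformed lowpass->bandpass
# in the s-plane, discretised by the bilinear transform with frequency
# pre-warping, and applied as cascaded second-order sections.  Zero-phase
# response is obtained by forward-reverse filtering with odd-reflection
# padding.  The analytic signal comes from the FFT half-spectrum method.

#' Construct an AnalyticSignal object
#'
#' Complex-valued band-limited signal: amplitude `A = Mod(values)` and phase
#' `theta = Arg(values)` in (-pi, pi] per (row, col, time, trial).
#'
#' @param values complex 4D array (row, col, time, trial).
#' @param fs sampling frequency, Hz.
#' @param band numeric: `c(f_lo, f_hi)` for band-pass methods or a single
#'   centre frequency for wavelet methods.
#' @param method filtering method used (`"hilbert"`, `"morlet"`, `"none"`).
#' @param edge_len number of samples at each end of the time axis considered
#'   unreliable (filter/wavelet transient length).
#' @return an object of class `analytic_signal`.
#' @export
analytic_signal <- function(values, fs, band, method = "none", edge_len = 0L) {
  d <- dim(values)
  if (length(d) == 3L) dim(values) <- d <- c(d, 1L)
  stopifnot(length(d) == 4L)
  structure(list(values = values, fs = fs, band = band, method = method,
                 edge_len = as.integer(edge_len)),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<analytic_signal> %d x %d grid, %d frames, %d trial(s), %s, band [%s] Hz\n",
    d[1], d[2], d[3], d[4], x$method, paste(signif(x$band, 4), collapse = ", ")))
  invisible(x)
}

# Butterworth band-pass as second-order sections ------------------------------

# n_poles total poles (even); prototype order n_poles/2
butter_bandpass_sos <- function(f_lo, f_hi, fs, n_poles = 8L) {
  stopifnot(0 < f_lo, f_lo < f_hi, f_hi < fs / 2, n_poles %% 2L == 0L)
  n <- n_poles / 2L                      # analog lowpass prototype order
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles, Re < 0
  # pre-warped band edges (bilinear transform with fs2 = 2)
  fs2 <- 2
  w1 <- 2 * fs2 * tan(pi * (f_lo / (fs / 2)) / fs2)
  w2 <- 2 * fs2 * tan(pi * (f_hi / (fs / 2)) / fs2)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)
  # lowpass -> bandpass in s-plane: each pole maps to a conjugate pair
  plp <- p * bw / 2
  pbp <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
  # bilinear transform: s -> 2*fs2*(z-1)/(z+1); the n zeros at s=0 map to
  # z=1 and n more appear at z=-1; overall gain fixed by normalisation below
  fs4 <- 2 * fs2
  pd <- (fs4 + pbp) / (fs4 - pbp)
  # group conjugate pole pairs into sections, one z=1 and one z=-1 zero each
  pd_pos <- pd[Im(pd) >= 0]
  ord <- order(-Mod(pd_pos))             # highest-Q sections last applied first
  pd_pos <- pd_pos[ord]
  sos <- matrix(0, nrow = n, ncol = 6)
  for (s in seq_len(n)) {
    pp <- pd_pos[s]
    # numerator (z-1)(z+1) = z^2 - 1; denominator (z-pp)(z-conj(pp))
    sos[s, 1:3] <- c(1, 0, -1)
    sos[s, 4:6] <- c(1, -2 * Re(pp), Mod(pp)^2)
  }
  # overall gain: normalise exact unit magnitude at band centre
  f0 <- sqrt(f_lo * f_hi)
  z0 <- exp(2i * pi * f0 / fs)
  h <- prod(apply(sos, 1, function(co)
    (co[1] * z0^2 + co[2] * z0 + co[3]) / (co[4] * z0^2 + co[5] * z0 + co[6])))
  sos[1, 1:3] <- sos[1, 1:3] / Mod(h)
  sos
}

# direct form II transposed, one second-order section
sosfilt1 <- function(co, x) {
  b <- co[1:3]; a <- co[4:6]
  b <- b / a[1]; a <- a / a[1]
  y <- numeric(length(x))
  z1 <- 0; z2 <- 0
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

sosfilt <- function(sos, x) {
  for (s in seq_len(nrow(sos))) x <- sosfilt1(sos[s, ], x)
  x
}

# zero-phase filtering: odd-reflection padding, forward then reverse pass
sosfiltfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * (2L * nrow(sos) + 1L) * 3L)
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(pre, x, post)
  xp <- sosfilt(sos, xp)
  xp <- rev(sosfilt(sos, rev(xp)))
  xp[(padlen + 1L):(padlen + n)]
}

# FFT analytic signal: zero negative frequencies, double positive ones
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Band-pass filter and extract the analytic signal (Butterworth + Hilbert)
#'
#' Filters each site/trial series with an 8th-order (8-pole) Butterworth
#' band-pass applied forward and reverse (zero phase distortion: maxima and
#' minima keep their timing), then forms the analytic signal
#' \eqn{A e^{i\theta}} via the Hilbert transform.
#'
#' @param rec a [recording()] with all channels valid.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param n_poles total filter order (default 8).
#' @return an [analytic_signal()].
#' @export
filter_hilbert <- function(rec, f_lo, f_hi, n_poles = 8L) {
  stopifnot(inherits(rec, "recording"))
  if (any(!rec$channel_mask))
    stop("recording has invalid channels; run interpolate_bad_channels() first")
  fs <- rec$fs
  if (!(0 < f_lo && f_lo < f_hi && f_hi < fs / 2))
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  d <- dim(rec$signal)
  if (d[3] < 3L * (n_poles + 1L))
    stop("time series too short for stable filtering")
  sos <- butter_bandpass_sos(f_lo, f_hi, fs, n_poles)
  out <- array(0i, d)
  for (p in seq_len(d[4])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    xf <- sosfiltfilt(sos, rec$signal[r, c, , p])
    out[r, c, , p] <- hilbert_analytic(xf)
  }
  edge <- min(d[3] %/% 2L, ceiling(2 * fs / f_lo))
  analytic_signal(out, fs = fs, band = c(f_lo, f_hi), method = "hilbert",
                  edge_len = edge)
}

#' Extract the analytic signal with a complex Morlet wavelet
#'
#' Convolves each site/trial series with a complex Morlet wavelet at centre
#' frequency `f_c`, yielding the analytic signal directly.  The wavelet's
#' temporal width is `n_cycles/(2*pi*f_c)`; the amplitude is normalised so a
#' unit cosine at `f_c` returns amplitude 1.
#'
#' @param rec a [recording()] with all channels valid.
#' @param f_c centre frequency in Hz, `0 < f_c < fs/2`.
#' @param n_cycles wavelet width in oscillation cycles (>= 3; default 6,
#'   a common time/frequency-resolution compromise).
#' @return an [analytic_signal()]; `edge_len` marks one wavelet half-width.
#' @export
filter_morlet <- function(rec, f_c, n_cycles = 6) {
  stopifnot(inherits(rec, "recording"))
  if (any(!rec$channel_mask))
    stop("recording has invalid channels; run interpolate_bad_channels() first")
  fs <- rec$fs
  if (!(0 < f_c && f_c < fs / 2)) stop("f_c must lie in (0, fs/2)")
  if (n_cycles < 3) stop("n_cycles must be >= 3")
  d <- dim(rec$signal)
  sigma_t <- n_cycles / (2 * pi * f_c)            # seconds
  half <- ceiling(3.5 * sigma_t * fs)             # samples
  if (2L * half + 1L > d[3]) stop("wavelet longer than the time series")
  tt <- (-half:half) / fs
  wav <- exp(2i * pi * f_c * tt) * exp(-tt^2 / (2 * sigma_t^2))
  wav <- wav * 2 / (fs * sigma_t * sqrt(2 * pi))  # unit response at f_c
  out <- array(0i, d)
  for (p in seq_len(d[4])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    out[r, c, , p] <- conv_same_complex(rec$signal[r, c, , p], wav)
  }
  analytic_signal(out, fs = fs, band = f_c, method = "morlet",
                  edge_len = half)
}

# 'same'-mode complex convolution via FFT
conv_same_complex <- function(x, w) {
  n <- length(x); m <- length(w); half <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  W <- stats::fft(c(w, rep(0i, nf - m)))
  full <- stats::fft(X * W, inverse = TRUE) / nf
  full[(half + 1L):(half + n)]
}

#' Split an analytic signal into phase and amplitude fields
#'
#' @param sig an [analytic_signal()].
#' @return list with `phase` (radians in (-pi, pi]; 0 where amplitude is 0),
#'   `amplitude` (non-negative), and `zero_mask` flagging zero-amplitude
#'   samples whose phase is undefined and set to 0 by convention.
#' @export
split_phase_amplitude <- function(sig) {
  stopifnot(inherits(sig, "analytic_signal"))
  A <- Mod(sig$values)
  theta <- Arg(sig$values)
  zero <- A == 0
  theta[zero] <- 0
  list(phase = theta, amplitude = A, zero_mask = zero)
}
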