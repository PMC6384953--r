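# Low-level DSP primitives shared by the detection, coupling and spectral
# modules. All zero-phase filtering is done in the frequency domain on a
# reflection-padded copy of the signal: the realized gains are real and even,
# so phase is exactly zero and time-reversal symmetry holds by construction.

#' Design a linear-phase (type I) FIR filter by least squares
#'
#' Amplitude response is fit on a dense frequency grid to the piecewise-linear
#' desired response given by `freq` (Hz, from 0 to Nyquist) and `gain` at those
#' breakpoints. This mirrors the two-way least-squares FIR convention used in
#' EEG tooling.
#'
#' @param order filter order (forced even; `order + 1` taps)
#' @param freq breakpoint frequencies in Hz, increasing, spanning 0..fs/2
#' @param gain desired amplitude at each breakpoint
#' @param fs sampling rate (Hz)
#' @param dont_care optional list of `c(f1, f2)` ranges (Hz) excluded from the
#'   fit (transition bands, as in the classic firls convention)
#' @return numeric vector of `order + 1` symmetric taps
#' @keywords internal
fir_ls_design <- function(order, freq, gain, fs, dont_care = NULL) {
  stopifnot(length(freq) == length(gain), !is.unsorted(freq),
            freq[1] >= 0, order >= 2)
  if (order %% 2 == 1) order <- order + 1
  M <- order / 2
  ngrid <- max(1024L, 16L * (M + 1L))
  w <- seq(0, pi, length.out = ngrid)
  f <- w * fs / (2 * pi)
  d <- stats::approx(freq, gain, xout = f, rule = 2)$y
  keep <- rep(TRUE, ngrid)
  for (dc in dont_care) keep <- keep & !(f > dc[1] & f < dc[2])
  # A(w) = c0 + sum_k c_k cos(k w); solve in the cosine basis
  X <- cbind(1, cos(outer(w[keep], seq_len(M))))
  cf <- stats::lm.fit(X, d[keep])$coefficients
  h <- numeric(order + 1)
  h[M + 1] <- cf[1]
  h[M + 1 + seq_len(M)] <- cf[-1] / 2
  h[M + 1 - seq_len(M)] <- cf[-1] / 2
  h
}

# Amplitude response of symmetric taps at angular frequencies w (radians/sample)
fir_amplitude <- function(h, w) {
  M <- (length(h) - 1) / 2
  k <- seq_len(M)
  drop(h[M + 1] + 2 * (cos(outer(w, k)) %*% h[M + 1 + k]))
}

# Squared magnitude of a digital Butterworth low-pass obtained by bilinear
# transform of the analog prototype (exact closed form, no pole arithmetic).
butter_lp_mag2 <- function(w, fc, fs, order) {
  wc <- tan(pi * fc / fs)
  r <- (tan(w / 2) / wc)^(2 * order)
  1 / (1 + r)
}

# Reflection (odd) padding as used by filtfilt-style routines
reflect_pad <- function(x, np) {
  n <- length(x)
  np <- min(np, n - 1)
  left <- 2 * x[1] - x[seq(np + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - np)]
  list(x = c(left, x, right), np = np)
}

# Apply a real, even frequency-domain gain to a signal with reflection padding.
# `gain_fun(w)` receives angular frequency in [0, pi] and must return the
# (zero-phase) gain. Exactly linear-phase-free: output is Re(ifft(fft * g)).
apply_zero_phase <- function(x, gain_fun, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, max(256L, ceiling(n / 10)))
  p <- reflect_pad(x, pad)
  # extend to a 2-3-5-smooth length (FFT cost blows up on rough lengths)
  L <- stats::nextn(length(p$x), c(2, 3, 5))
  xp <- c(p$x, rep(p$x[length(p$x)], L - length(p$x)))
  w <- 2 * pi * (0:(L - 1)) / L
  w <- ifelse(w > pi, 2 * pi - w, w)  # fold to [0, pi]; gain even in w
  g <- gain_fun(w)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / L
  y[(p$np + 1):(p$np + n)]
}

#' Zero-phase band-pass with a two-way least-squares FIR filter
#'
#' The filter order follows the convention `3 * round(fs / lo)`; application is
#' two-way (forward and backward), i.e. the realized gain is the squared
#' amplitude response.
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param lo,hi band edges (Hz)
#' @param rolloff transition width (Hz) on each side
#' @param order optional override of the filter order
#' @return filtered signal, same length
#' @keywords internal
bandpass_fir <- function(x, fs, lo, hi, rolloff = 0.5, order = NULL) {
  nyq <- fs / 2
  stopifnot(lo > 0, hi > lo, hi < nyq)
  if (is.null(order)) order <- 3L * round(fs / lo)
  f1 <- max(0, lo - rolloff); f2 <- min(nyq, hi + rolloff)
  h <- fir_ls_design(order, c(0, f1, lo, hi, f2, nyq), c(0, 0, 1, 1, 0, 0), fs,
                     dont_care = list(c(f1, lo), c(hi, f2)))
  apply_zero_phase(x, function(w) fir_amplitude(h, w)^2,
                   pad = min(length(x) - 1, 3L * length(h)))
}

# Zero-phase Butterworth low-pass (single-pass magnitude of the given order)
lowpass_butter <- function(x, fs, fc, order = 4) {
  apply_zero_phase(x, function(w) sqrt(butter_lp_mag2(w, fc, fs, order)))
}

#' Downsample a signal to a target rate with anti-alias low-pass
#'
#' The target rate must divide the input rate. An anti-alias zero-phase
#' low-pass at 80% of the new Nyquist precedes decimation.
#' @keywords internal
decimate_signal <- function(x, fs, target_fs) {
  if (fs == target_fs) return(x)
  fac <- fs / target_fs
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("target_fs must divide fs (got fs=", fs, ", target_fs=", target_fs, ")")
  fac <- as.integer(round(fac))
  fc <- 0.8 * target_fs / 2
  y <- apply_zero_phase(x, function(w) {
    f <- w * fs / (2 * pi)
    g <- rep(1, length(f))
    tr <- f > fc
    g[tr] <- pmax(0, 1 - (f[tr] - fc) / (target_fs / 2 - fc))
    g
  })
  y[seq(1, length(y), by = fac)]
}

# Analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Instantaneous phase at arbitrary times of a band-limited signal sampled at fs
instantaneous_phase <- function(x, fs, t0 = 0) {
  z <- analytic_signal(x)
  function(times) {
    idx <- (times - t0) * fs + 1
    i0 <- pmax(1, pmin(length(x) - 1, floor(idx)))
    frac <- idx - i0
    # interpolate the analytic signal (not the wrapped phase)
    zi <- z[i0] * (1 - frac) + z[i0 + 1] * frac
    Arg(zi)
  }
}

#' Morlet wavelet power
#'
#' Time-frequency power via frequency-domain Gaussian kernels (analytic Morlet
#' with a fixed number of cycles: spectral sd = f / cycles).
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param freqs frequencies of interest (Hz)
#' @param cycles wavelet width in cycles
#' @return matrix `length(freqs) x length(x)` of power
#' @keywords internal
morlet_power <- function(x, fs, freqs, cycles = 7) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, n - n0)))
  fr <- (0:(n - 1)) * fs / n
  out <- matrix(0, length(freqs), n0)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sf <- f0 / cycles
    K <- exp(-((fr - f0)^2) / (2 * sf^2))
    K[fr > fs / 2] <- 0  # analytic: keep positive frequencies only
    wv <- stats::fft(X * K, inverse = TRUE) / n
    out[i, ] <- Mod(wv[seq_len(n0)])^2
  }
  out
}

# ---- Discrete prolate spheroidal sequences -------------------------------

.dpss_cache <- new.env(parent = emptyenv())

#' Slepian (DPSS) tapers
#'
#' Computed from the symmetric tridiagonal formulation. For long windows the
#' tapers are computed exactly at 1024 points and spline-interpolated to the
#' requested length (then renormalized), which is the standard approach for
#' large N and is accurate to ~1e-3 in taper shape.
#'
#' @param N window length (samples)
#' @param TW time-bandwidth product
#' @param K number of tapers
#' @return `N x K` matrix, columns unit-energy tapers ordered by concentration
#' @keywords internal
dpss_tapers <- function(N, TW, K) {
  key <- paste(N, TW, K, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  N0 <- min(N, 1024L)
  w <- TW / N0
  t <- 0:(N0 - 1)
  diag_el <- ((N0 - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (N0 - t[-1]) / 2
  A <- matrix(0, N0, N0)
  A[cbind(t + 1, t + 1)] <- diag_el
  A[cbind(2:N0, 1:(N0 - 1))] <- off
  A[cbind(1:(N0 - 1), 2:N0)] <- off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(K), drop = FALSE]
  if (N > N0) {
    Vi <- apply(V, 2, function(v)
      stats::spline(x = seq(0, 1, length.out = N0), y = v,
                    xout = seq(0, 1, length.out = N))$y)
    V <- Vi
  }
  # unit energy; deterministic sign convention
  V <- apply(V, 2, function(v) v / sqrt(sum(v^2)))
  for (k in seq_len(K)) {
    s <- if (k %% 2 == 1) sum(V[, k]) else sum(V[seq_len(ceiling(N / 2)), k] *
                                                 seq_len(ceiling(N / 2)))
    if (s < 0) V[, k] <- -V[, k]
  }
  .dpss_cache[[key]] <- V
  V
}
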