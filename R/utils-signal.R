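# Shared signal-processing helpers.

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, as applied to the GSR
#' signal (5 Hz) before conditioning and to the physiology signals (0.5 Hz)
#' before tCCA embedding.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param cutoff low-pass cutoff (Hz), below Nyquist.
#' @param order filter order (default 4).
#' @return filtered series of the same length.
#' @export
zero_phase_lowpass <- function(x, fs, cutoff, order = 4) {
  bw_filtfilt(x, fs, cutoff, "low", order)
}

# Zero-phase Butterworth low/high-pass via filtfilt.
bw_filtfilt <- function(x, fs, cutoff, type = c("low", "high"), order = 4) {
  type <- match.arg(type)
  w <- cutoff * 2 / fs
  if (w >= 1) stop("cutoff at or above Nyquist (", fs / 2, " Hz)")
  if (w <= 0) stop("cutoff must be positive")
  flt <- signal::butter(order, w, type = type)
  signal::filtfilt(flt, x)
}

# Zero-phase band-pass as a high-pass / low-pass cascade; numerically safer
# than a single narrow band-pass design at very low normalized edges.
bp_filtfilt <- function(x, fs, band, order_high = 2, order_low = 4) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  x <- bw_filtfilt(x, fs, band[1], "high", order_high)
  bw_filtfilt(x, fs, band[2], "low", order_low)
}

# Full linear convolution via FFT, zero-padded to a highly composite length
# (prime-length mixed-radix FFTs degrade to O(n^2)).
fft_conv <- function(x, k) {
  n_out <- length(x) + length(k) - 1L
  N <- stats::nextn(n_out, 2L)
  X <- stats::fft(c(x, numeric(N - length(x))))
  K <- stats::fft(c(k, numeric(N - length(k))))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / N
  y[seq_len(n_out)]
}

# Linear interpolation for strictly increasing abscissae (skips tie handling).
interp1 <- function(x, y, xout, rule = 2) {
  stats::approx(x, y, xout = xout, rule = rule, ties = "ordered")$y
}

# Linear interpolation from a uniform grid (x[k] at time (k-1)/fs_in) onto
# arbitrary times, edge values held; pure arithmetic, no search. The index
# plan can be precomputed once and shared across signals on the same grids.
interp_plan <- function(n_in, fs_in, t_out) {
  pos <- t_out * fs_in + 1
  pos[pos < 1] <- 1
  pos[pos > n_in] <- n_in
  i <- floor(pos)
  i[i >= n_in] <- n_in - 1L
  list(i = as.integer(i), frac = pos - i)
}

interp_apply <- function(x, plan) {
  x[plan$i] * (1 - plan$frac) + x[plan$i + 1L] * plan$frac
}

interp_uniform <- function(x, fs_in, t_out) {
  interp_apply(x, interp_plan(length(x), fs_in, t_out))
}

# FFT-based linear-phase FIR filtering with group-delay compensation.
# h must be a symmetric (linear-phase) odd-length kernel.
fir_zerophase <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (L >= n) stop("FIR kernel (", L, " taps) too long for series length ", n)
  d <- (L - 1L) / 2L
  y <- fft_conv(x, h)
  y[(d + 1L):(d + n)]
}

# Batched column-wise version of fir_zerophase (one FFT plan via mvfft).
fir_zerophase_mat <- function(X, h) {
  n <- nrow(X)
  L <- length(h)
  if (L >= n) stop("FIR kernel (", L, " taps) too long for series length ", n)
  d <- (L - 1L) / 2L
  N <- stats::nextn(n + L - 1L, 2L)
  Xp <- rbind(X, matrix(0, N - n, ncol(X)))
  K <- stats::fft(c(h, numeric(N - L)))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * K, inverse = TRUE)) / N
  Y[(d + 1L):(d + n), , drop = FALSE]
}

# Hamming-rule linear-phase FIR low-pass (odd tap count).
fir_lowpass <- function(fs, cutoff, transition_bw) {
  ord <- ceiling(3.3 * fs / transition_bw)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, cutoff * 2 / fs, type = "low")
}

# Delay a series by `lag_s` seconds: y(t) = x(t - lag). Edge values are held
# (rule = 2). Integer-sample lags reduce to an exact index shift.
shift_series <- function(x, lag_s, fs) {
  if (lag_s == 0) return(x)
  n <- length(x)
  k <- lag_s * fs
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    if (k >= n || -k >= n) stop("lag exceeds series duration")
    if (k > 0) return(c(rep(x[1], k), x[seq_len(n - k)]))
    return(c(x[(1 - k):n], rep(x[n], -k)))
  }
  interp1(seq_len(n), x, xout = seq_len(n) - k)
}

# Column-wise z-score.
zscore <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, zscore))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant series")
  (x - mean(x)) / s
}

# Band-limited Gaussian noise with unit standard deviation.
band_noise <- function(n, fs, band = c(0.01, 0.5)) {
  x <- stats::rnorm(n)
  hi <- min(band[2], 0.45 * fs)
  x <- bp_filtfilt(x, fs, c(band[1], hi))
  x / stats::sd(x)
}

# Amplitude of a sinusoidal component near f0 from the periodogram.
spectral_amplitude <- function(x, fs, f0) {
  n <- length(x)
  sp <- stats::fft(x - mean(x))
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  i <- half[which.min(abs(freqs[half] - f0))]
  2 * Mod(sp[i]) / n
}
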