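# Canonical hemodynamic response model and stimulus regressor construction.

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention double gamma: a gamma density peaking at `peak` seconds minus
#' a gamma density peaking at `undershoot` seconds scaled by `1/ratio`. Values
#' for `t < 0` are zero. The raw (unnormalized) shape is returned; stimulus
#' regressors built from it are peak-normalized by [event_regressor()] so that
#' a beta of 1 corresponds to a unit peak response.
#'
#' @param t time points in seconds.
#' @param peak time-to-peak of the positive lobe (s); gamma shape with rate 1.
#' @param undershoot time-to-peak of the undershoot lobe (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(peak > 0, undershoot > 0, ratio > 0)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Stimulus regressor: canonical HRF convolved with a boxcar
#'
#' Places a `boxcar_width`-second box at each onset and convolves with the
#' canonical double-gamma HRF. The combined kernel (HRF x boxcar) is
#' normalized to unit peak, so the regression coefficient of this column is
#' the peak evoked amplitude in the units of the response variable.
#'
#' @param onsets event onset times (s).
#' @param n number of samples in the output series.
#' @param fs sampling rate (Hz).
#' @param hrf_params list with `peak`, `undershoot`, `ratio` (see
#'   [canonical_hrf()]).
#' @param boxcar_width width of the boxcar in seconds (default 3).
#' @return numeric vector of length `n`.
#' @export
event_regressor <- function(onsets, n, fs,
                            hrf_params = list(peak = 6, undershoot = 16,
                                              ratio = 6),
                            boxcar_width = 3) {
  stopifnot(n >= 1, fs > 0, boxcar_width > 0)
  k <- hrf_boxcar_kernel(fs, hrf_params, boxcar_width)
  x <- numeric(n)
  idx <- round(onsets * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  for (i in idx) x[i] <- x[i] + 1
  fft_conv(x, k)[seq_len(n)]
}

# Peak-normalized HRF (x) boxcar kernel sampled at fs.
hrf_boxcar_kernel <- function(fs, hrf_params, boxcar_width) {
  dt <- 1 / fs
  th <- seq(0, 32, by = dt)
  h <- canonical_hrf(th, hrf_params$peak %||% 6, hrf_params$undershoot %||% 16,
                     hrf_params$ratio %||% 6)
  box <- rep(1, max(1L, round(boxcar_width * fs)))
  k <- fft_conv(h, box)
  k / max(k)
}
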