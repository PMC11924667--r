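# Preprocessing: raw dual-wavelength intensities -> hemoglobin concentrations.
#
# Two distinct paths are supported, mirroring standard practice for this kind
# of recording:
#   * block-averaging path: OD -> SCI pruning -> TDDR -> MBLL ->
#     short-channel subtraction -> 0.02-0.4 Hz bandpass (native rate);
#   * GLM path: OD -> SCI pruning -> MBLL -> anti-aliased resampling to the
#     analysis rate, with NO temporal filtering, motion correction or
#     short-channel subtraction (those effects are modelled as regressors).

#' Raw fNIRS scan container
#'
#' @param intensity numeric array `channel x wavelength x time` of strictly
#'   positive intensities (arbitrary units).
#' @param sample_rate sampling rate (Hz).
#' @param channels channel table: data frame with columns `channel`, `source`,
#'   `detector`, `separation_mm`, `is_short`, `roi`.
#' @param wavelengths the two wavelengths (nm).
#' @return object of class `raw_scan`.
#' @export
raw_scan <- function(intensity, sample_rate, channels,
                     wavelengths = c(760, 850)) {
  stopifnot(length(dim(intensity)) == 3, dim(intensity)[2] == 2,
            length(wavelengths) == 2, sample_rate > 0,
            nrow(channels) == dim(intensity)[1])
  req <- c("channel", "separation_mm", "is_short", "roi")
  if (!all(req %in% names(channels)))
    stop("channel table must have columns: ", paste(req, collapse = ", "))
  structure(list(intensity = intensity, sample_rate = sample_rate,
                 channels = channels, wavelengths = wavelengths),
            class = "raw_scan")
}

#' Hemoglobin concentration time-series container
#'
#' @param conc numeric array `channel x chroma(HbO, HbR) x time` of molar
#'   concentration changes (uM).
#' @param sample_rate sampling rate (Hz).
#' @param channels channel table (see [raw_scan()]).
#' @return object of class `hemo_ts`.
#' @export
hemo_ts <- function(conc, sample_rate, channels) {
  stopifnot(length(dim(conc)) == 3, dim(conc)[2] == 2, sample_rate > 0,
            nrow(channels) == dim(conc)[1])
  if (any(!is.finite(conc))) stop("non-finite concentration values")
  dimnames(conc)[[2]] <- CHROMA
  structure(list(conc = conc, sample_rate = sample_rate, channels = channels),
            class = "hemo_ts")
}

n_samples <- function(x) dim(x$conc %||% x$od %||% x$intensity)[3]

time_axis <- function(x) (seq_len(n_samples(x)) - 1) / x$sample_rate

#' Preprocessing configuration
#'
#' @param sci_threshold scalp-coupling-index pruning threshold (channels with
#'   SCI below it are removed).
#' @param sci_highpass_cutoff,sci_transition_bw FIR high-pass cutoff and
#'   transition bandwidth (Hz) applied before the inter-wavelength correlation.
#' @param ppf partial pathlength factor used in the modified Beer-Lambert law.
#' @param analysis_rate target sampling rate (Hz) for GLM analysis.
#' @param blockavg_band bandpass edges (Hz) for the block-averaging path.
#' @param extinction 2x2 extinction-coefficient matrix (rows = wavelengths,
#'   cols = HbO/HbR; natural-log units, 1/(mm*uM)); defaults to the standard
#'   760/850 nm tabulation.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(sci_threshold = 0.7,
                              sci_highpass_cutoff = 1.35,
                              sci_transition_bw = 0.1,
                              ppf = 0.1,
                              analysis_rate = 0.6,
                              blockavg_band = c(0.02, 0.4),
                              extinction = extinction_coefficients(c(760, 850))) {
  stopifnot(sci_threshold >= 0, sci_threshold <= 1, sci_highpass_cutoff > 0,
            sci_transition_bw > 0, ppf > 0, analysis_rate > 0,
            length(blockavg_band) == 2)
  structure(list(sci_threshold = sci_threshold,
                 sci_highpass_cutoff = sci_highpass_cutoff,
                 sci_transition_bw = sci_transition_bw, ppf = ppf,
                 analysis_rate = analysis_rate, blockavg_band = blockavg_band,
                 extinction = extinction),
            class = "preprocess_config")
}

#' Molar extinction coefficients for HbO/HbR
#'
#' Standard tabulated values (Gratzer/Prahl compilation) at 760 and 850 nm,
#' converted from log10 cm^-1 M^-1 to natural-log mm^-1 uM^-1 to match
#' natural-log optical densities, millimetre separations and micromolar
#' concentrations.
#'
#' @param wavelengths two distinct wavelengths (nm); 760 and 850 are tabulated.
#' @return 2x2 matrix, rows = wavelengths, columns = `hbo`, `hbr`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  if (length(wavelengths) != 2 || wavelengths[1] == wavelengths[2])
    stop("two distinct wavelengths are required (extinction matrix singular)")
  tab <- rbind("760" = c(hbo = 586.00, hbr = 1548.52),
               "850" = c(hbo = 1058.00, hbr = 691.32))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("no tabulated extinction coefficients for wavelengths ",
         paste(setdiff(key, rownames(tab)), collapse = ", "), " nm")
  out <- tab[key, , drop = FALSE] * log(10) * 1e-7  # cm^-1 M^-1 -> mm^-1 uM^-1
  rownames(out) <- key
  out
}

#' Convert raw intensities to optical densities
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, so each OD series
#' has zero mean in log space.
#'
#' @param scan a [raw_scan()].
#' @return object of class `od_series` (same layout, `od` array instead of
#'   `intensity`).
#' @export
intensity_to_od <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  I <- scan$intensity
  bad <- which(apply(I <= 0, 1, any))
  if (length(bad) > 0)
    stop("non-positive intensity in channel(s): ",
         paste(scan$channels$channel[bad], collapse = ", "))
  m <- apply(I, c(1, 2), mean)
  od <- -log(I / as.vector(m))  # (channel, wavelength) means recycle over time
  structure(list(od = od, sample_rate = scan$sample_rate,
                 channels = scan$channels, wavelengths = scan$wavelengths),
            class = "od_series")
}

# Linear-phase FIR high-pass used by the SCI; taps from the Hamming-window
# rule N ~= 3.3 / (transition bandwidth / fs), forced odd.
sci_fir <- function(fs, cutoff, transition_bw) {
  if (cutoff >= fs / 2)
    stop("SCI high-pass cutoff ", cutoff, " Hz is at/above Nyquist (",
         fs / 2, " Hz); compute the SCI at the native rate")
  ord <- ceiling(3.3 * fs / transition_bw)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, cutoff * 2 / fs, type = "high")
}

#' Scalp coupling index and channel keep/drop mask
#'
#' SCI = Pearson correlation between the two wavelengths' high-pass-filtered
#' optical densities (linear-phase FIR, cutoff and transition bandwidth from
#' the configuration). Must be computed at the native sampling rate, before
#' any downsampling. Channels with SCI below the threshold are flagged for
#' removal.
#'
#' @param od an [intensity_to_od()] result.
#' @param cfg a [preprocess_config()].
#' @return data frame with columns `channel`, `sci`, `keep`.
#' @export
scalp_coupling_index <- function(od, cfg = preprocess_config()) {
  stopifnot(inherits(od, "od_series"))
  h <- sci_fir(od$sample_rate, cfg$sci_highpass_cutoff, cfg$sci_transition_bw)
  if (length(h) >= n_samples(od))
    stop("series too short for the SCI FIR filter (", length(h), " taps)")
  nch <- dim(od$od)[1]
  n <- n_samples(od)
  M <- matrix(aperm(od$od, c(3, 1, 2)), n, nch * 2L)  # wl1 cols, then wl2
  Mf <- fir_zerophase_mat(M, h)
  sci <- vapply(seq_len(nch), function(c_i) {
    a <- Mf[, c_i]
    b <- Mf[, nch + c_i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  keep <- !is.na(sci) & sci >= cfg$sci_threshold
  data.frame(channel = od$channels$channel, sci = sci, keep = keep)
}

#' Drop pruned channels from an OD or hemoglobin series
#'
#' @param x an `od_series` or `hemo_ts`.
#' @param keep logical vector (one entry per channel) of channels to retain.
#' @return `x` restricted to the kept channels; dropped channel names are in
#'   `attr(, "dropped")`.
#' @export
prune_channels <- function(x, keep) {
  stopifnot(length(keep) == nrow(x$channels))
  dropped <- x$channels$channel[!keep]
  if (!any(keep)) stop("channel pruning removed every channel")
  fld <- if (inherits(x, "od_series")) "od" else "conc"
  x[[fld]] <- x[[fld]][keep, , , drop = FALSE]
  x$channels <- x$channels[keep, , drop = FALSE]
  rownames(x$channels) <- NULL
  attr(x, "dropped") <- dropped
  x
}

#' Temporal derivative distribution repair (TDDR) motion correction
#'
#' Robust iterative reweighting (Tukey biweight, tuning constant 4.685) of the
#' temporal derivative of the low-frequency (< 0.5 Hz) part of the signal,
#' followed by reintegration and restoration of the untouched high-frequency
#' part. Constant series are returned unchanged. Output length equals input
#' length.
#'
#' @param x numeric vector, `od_series`, or `hemo_ts` (applied per series).
#' @param sample_rate sampling rate (Hz); taken from the object when present.
#' @param tol convergence tolerance on the robust location estimate.
#' @param ... unused.
#' @return corrected object of the same type/shape.
#' @export
tddr <- function(x, sample_rate = NULL, tol = 1e-9, ...) UseMethod("tddr")

#' @export
tddr.default <- function(x, sample_rate = NULL, tol = 1e-9, ...) {
  stopifnot(is.numeric(x), !is.null(sample_rate))
  if (stats::sd(x) == 0) return(x)
  m0 <- mean(x)
  y <- x - m0
  if (sample_rate > 1) {
    y_low <- bw_filtfilt(y, sample_rate, 0.5, "low", order = 3)
  } else {
    y_low <- y
  }
  y_high <- y - y_low
  dv <- diff(y_low)
  tune <- 4.685
  w <- rep(1, length(dv))
  mu <- Inf
  for (it in seq_len(50L)) {
    mu0 <- mu
    mu <- sum(w * dv) / sum(w)
    dev <- dv - mu
    sigma <- 1.4826 * stats::median(abs(dev))
    if (sigma == 0) break
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (abs(r) < 1))^2
    if (is.finite(mu0) && abs(mu - mu0) <= tol * max(abs(mu), abs(mu0), 1))
      break
  }
  new_dv <- w * (dv - mu)
  y_corr <- cumsum(c(0, new_dv))
  y_corr <- y_corr - mean(y_corr)
  y_corr + y_high + m0
}

#' @export
tddr.od_series <- function(x, sample_rate = NULL, tol = 1e-9, ...) {
  fs <- sample_rate %||% x$sample_rate
  for (c_i in seq_len(dim(x$od)[1]))
    for (w in 1:2)
      x$od[c_i, w, ] <- tddr.default(x$od[c_i, w, ], fs, tol)
  x
}

#' @export
tddr.hemo_ts <- function(x, sample_rate = NULL, tol = 1e-9, ...) {
  fs <- sample_rate %||% x$sample_rate
  for (c_i in seq_len(dim(x$conc)[1]))
    for (k in 1:2)
      x$conc[c_i, k, ] <- tddr.default(x$conc[c_i, k, ], fs, tol)
  x
}

#' Optical density to hemoglobin concentrations (modified Beer-Lambert law)
#'
#' Per time point and channel, solves the 2x2 system
#' `dOD_lambda = (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR) * d * PPF`
#' with source-detector distance `d` from the channel table and the partial
#' pathlength factor from the configuration.
#'
#' @param od an `od_series`.
#' @param cfg a [preprocess_config()].
#' @return a [hemo_ts()] in uM.
#' @export
od_to_hemoglobin <- function(od, cfg = preprocess_config()) {
  stopifnot(inherits(od, "od_series"))
  E <- cfg$extinction
  if (abs(det(E)) < .Machine$double.eps)
    stop("singular extinction matrix (duplicate wavelengths?)")
  Einv <- solve(E)
  nch <- dim(od$od)[1]
  n <- dim(od$od)[3]
  conc <- array(NA_real_, dim = c(nch, 2L, n),
                dimnames = list(od$channels$channel, CHROMA, NULL))
  for (c_i in seq_len(nch)) {
    scale <- od$channels$separation_mm[c_i] * cfg$ppf
    conc[c_i, , ] <- (Einv %*% od$od[c_i, , ]) / scale
  }
  hemo_ts(conc, od$sample_rate, od$channels)
}

#' Band-pass filter and/or resample a hemoglobin series
#'
#' When `band` is given, applies a zero-phase Butterworth band-pass (high-pass
#' + low-pass cascade). When `target_rate` is given, applies an anti-aliasing
#' low-pass at 80% of the target Nyquist and interpolates onto the new uniform
#' time axis. The GLM path uses `target_rate` only (no temporal filtering);
#' the block-averaging path uses `band` only.
#'
#' @param hemo a `hemo_ts`.
#' @param band numeric length-2 band edges (Hz) or `NULL`.
#' @param target_rate new sampling rate (Hz) or `NULL`.
#' @return a `hemo_ts` at the (possibly new) rate.
#' @export
bandpass_and_resample <- function(hemo, band = NULL, target_rate = NULL) {
  stopifnot(inherits(hemo, "hemo_ts"))
  fs <- hemo$sample_rate
  if (!is.null(band) && !is.null(target_rate) && band[2] >= target_rate / 2)
    stop("band upper edge (", band[2], " Hz) must be below the target ",
         "Nyquist (", target_rate / 2, " Hz)")
  if (!is.null(target_rate) && target_rate >= fs)
    stop("target_rate must be below the current rate")
  x <- hemo$conc
  if (!is.null(band)) {
    for (c_i in seq_len(dim(x)[1]))
      for (k in 1:2)
        x[c_i, k, ] <- bp_filtfilt(x[c_i, k, ], fs, band)
  }
  if (!is.null(target_rate)) {
    n_old <- dim(x)[3]
    t_new <- seq(0, (n_old - 1) / fs, by = 1 / target_rate)
    # anti-alias: linear-phase FIR at 80% of the target Nyquist (zero-phase),
    # batched over channel x chroma; means removed/restored around the filter
    h <- fir_lowpass(fs, 0.8 * target_rate / 2,
                     transition_bw = 0.4 * target_rate / 2)
    nch <- dim(x)[1]
    M <- matrix(aperm(x, c(3, 1, 2)), n_old, nch * 2L)
    mu <- colMeans(M)
    Mf <- sweep(fir_zerophase_mat(sweep(M, 2, mu), h), 2, mu, `+`)
    y <- array(NA_real_, dim = c(nch, 2L, length(t_new)),
               dimnames = dimnames(x))
    for (c_i in seq_len(nch))
      for (k in 1:2)
        y[c_i, k, ] <- interp_uniform(Mf[, (k - 1L) * nch + c_i], fs, t_new)
    x <- y
    fs <- target_rate
  }
  hemo_ts(x, fs, hemo$channels)
}

#' Subtract the scaled short-channel reference from long channels
#'
#' The reference per chroma is the mean of surviving short channels. Each long
#' channel is reduced by its least-squares scaling of the reference, so the
#' residual is orthogonal to the reference. Used only on the block-averaging
#' path; the GLM path models short channels as regressors instead.
#'
#' @param hemo a `hemo_ts` containing both long and short channels.
#' @return a `hemo_ts` (long channels corrected, short channels untouched);
#'   the fitted scales are in `attr(, "ss_scale")`. If no short channels
#'   survive, the input is returned with a warning.
#' @export
short_channel_subtract <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_ts"))
  short <- hemo$channels$is_short
  if (!any(short)) {
    warning("no short channels available; returning input unchanged")
    return(hemo)
  }
  scales <- matrix(NA_real_, sum(!short), 2,
                   dimnames = list(hemo$channels$channel[!short], CHROMA))
  for (k in 1:2) {
    ref <- apply(hemo$conc[short, k, , drop = FALSE], 3, mean)
    denom <- sum(ref^2)
    li <- which(!short)
    for (j in seq_along(li)) {
      y <- hemo$conc[li[j], k, ]
      a <- if (denom > 0) sum(y * ref) / denom else 0
      hemo$conc[li[j], k, ] <- y - a * ref
      scales[j, k] <- a
    }
  }
  attr(hemo, "ss_scale") <- scales
  hemo
}

#' GLM-path preprocessing: prune, convert, resample — no filtering
#'
#' OD conversion, SCI pruning at the native rate, modified Beer-Lambert
#' conversion, anti-aliased resampling to the analysis rate. No bandpass, no
#' motion correction, no short-channel subtraction: nuisance structure is left
#' in the data for the GLM regressors.
#'
#' @param scan a [raw_scan()].
#' @param cfg a [preprocess_config()].
#' @return list with `hemo` (analysis-rate `hemo_ts`), `sci` (SCI table) and
#'   `dropped` (channel names pruned).
#' @export
preprocess_for_glm <- function(scan, cfg = preprocess_config()) {
  od <- intensity_to_od(scan)
  sci <- scalp_coupling_index(od, cfg)
  od <- prune_channels(od, sci$keep)
  hemo <- od_to_hemoglobin(od, cfg)
  hemo <- bandpass_and_resample(hemo, band = NULL,
                                target_rate = cfg$analysis_rate)
  list(hemo = hemo, sci = sci, dropped = attr(od, "dropped"))
}

#' Block-averaging-path preprocessing
#'
#' OD conversion, SCI pruning, TDDR motion correction, modified Beer-Lambert
#' conversion, short-channel subtraction, 0.02-0.4 Hz zero-phase bandpass.
#' Runs at the native sampling rate (the band's upper edge exceeds the
#' analysis-rate Nyquist, so no resampling is applied on this path).
#'
#' @inheritParams preprocess_for_glm
#' @return list with `hemo` (native-rate corrected `hemo_ts`), `sci`,
#'   `dropped`.
#' @export
preprocess_for_blockavg <- function(scan, cfg = preprocess_config()) {
  od <- intensity_to_od(scan)
  sci <- scalp_coupling_index(od, cfg)
  od <- prune_channels(od, sci$keep)
  od <- tddr(od)
  hemo <- od_to_hemoglobin(od, cfg)
  if (any(hemo$channels$is_short))
    hemo <- short_channel_subtract(hemo)
  hemo <- bandpass_and_resample(hemo, band = cfg$blockavg_band,
                                target_rate = NULL)
  list(hemo = hemo, sci = sci, dropped = attr(od, "dropped"))
}
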