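# Epoch extraction and condition-wise block averaging with 95% CIs.

#' Extract stimulus-locked epochs from a multichannel series
#'
#' @param x numeric matrix `time x series` (columns are channels, ROIs or
#'   physiology signals), or a numeric vector.
#' @param sample_rate sampling rate (Hz); time 0 is the first sample.
#' @param schedule event schedule (`onset`, `duration`, `condition`).
#' @param window epoch window in seconds relative to onset, default `c(-1, 15)`.
#' @return list per condition with `epochs` (array `epoch x time x series`),
#'   plus `time` (epoch time axis) and `n_dropped` (epochs overlapping a
#'   recording edge, excluded and counted).
#' @export
extract_epochs <- function(x, sample_rate, schedule, window = c(-1, 15)) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(window[1] < 0 || window[1] == 0, window[2] > window[1])
  n <- nrow(x)
  # sample offsets covering the window (the grid rarely hits it exactly)
  offs <- seq(floor(window[1] * sample_rate),
              ceiling(window[2] * sample_rate))
  t_epoch <- offs / sample_rate
  out <- list()
  n_dropped <- 0L
  for (cond in unique(schedule$condition)) {
    onsets <- schedule$onset[schedule$condition == cond]
    idx0 <- round(onsets * sample_rate) + 1L
    ok <- (idx0 + offs[1]) >= 1L & (idx0 + offs[length(offs)]) <= n
    n_dropped <- n_dropped + sum(!ok)
    idx0 <- idx0[ok]
    ep <- array(NA_real_, dim = c(length(idx0), length(offs), ncol(x)))
    for (e in seq_along(idx0)) ep[e, , ] <- x[idx0[e] + offs, , drop = FALSE]
    dimnames(ep) <- list(NULL, NULL, colnames(x))
    out[[cond]] <- ep
  }
  structure(out, time = t_epoch, n_dropped = n_dropped)
}

#' Average epochs with baseline correction and a 95% confidence band
#'
#' Each epoch is baseline-corrected by subtracting its mean over the pre-onset
#' interval (epoch time < 0); when the window contains no pre-onset samples no
#' baseline is removed. The confidence half-width is `1.96 x SEM` across
#' epochs.
#'
#' @param epochs array `epoch x time x series` (as from [extract_epochs()]).
#' @param t_epoch epoch time axis (s).
#' @return list with `mean` and `ci95` (`time x series` matrices) and
#'   `n_epochs`.
#' @export
average_epochs <- function(epochs, t_epoch) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[2] == length(t_epoch))
  ne <- dim(epochs)[1]
  if (ne == 0) stop("no epochs to average")
  pre <- which(t_epoch < 0)
  if (length(pre) > 0) {
    base <- apply(epochs[, pre, , drop = FALSE], c(1, 3), mean)
    for (e in seq_len(ne))
      epochs[e, , ] <- sweep(epochs[e, , , drop = FALSE], 3, base[e, ], `-`)
  }
  m <- apply(epochs, c(2, 3), mean)
  se <- apply(epochs, c(2, 3), stats::sd) / sqrt(ne)
  se[is.na(se)] <- 0
  list(mean = m, ci95 = 1.96 * se, n_epochs = ne)
}

#' Condition-wise evoked response (block average)
#'
#' Extracts epochs in `window` around every event, drops (and counts) epochs
#' overlapping a recording edge, baseline-corrects each epoch on the pre-onset
#' interval, and averages per condition with a 1.96 x SEM confidence band.
#' Errors if a condition has zero usable epochs.
#'
#' @inheritParams extract_epochs
#' @return object of class `evoked_response`: list per condition of
#'   `mean`/`ci95` (`time x series`) and `n_epochs`, plus `time` and
#'   `n_dropped` attributes.
#' @export
extract_epochs_and_average <- function(x, sample_rate, schedule,
                                       window = c(-1, 15)) {
  eps <- extract_epochs(x, sample_rate, schedule, window)
  t_epoch <- attr(eps, "time")
  out <- lapply(names(eps), function(cond) {
    if (dim(eps[[cond]])[1] == 0)
      stop("no usable epochs for condition '", cond, "'")
    average_epochs(eps[[cond]], t_epoch)
  })
  names(out) <- names(eps)
  structure(out, time = t_epoch, n_dropped = attr(eps, "n_dropped"),
            class = "evoked_response")
}

#' Pulse-respiration quotient
#'
#' Element-wise heart rate divided by respiration rate. Samples with
#' non-positive respiration are masked to `NA` with a warning.
#'
#' @param heart_rate heart-rate series (bpm).
#' @param respiration respiration-rate series (breaths/min), same length and
#'   sampling.
#' @return numeric PRQ series.
#' @export
compute_prq <- function(heart_rate, respiration) {
  stopifnot(length(heart_rate) == length(respiration))
  bad <- respiration <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive respiration masked to NA")
    respiration[bad] <- NA_real_
  }
  heart_rate / respiration
}
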