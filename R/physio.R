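# Physiology regressor conditioning, per-channel lag optimization, and
# temporally embedded canonical correlation analysis (tCCA).

#' Lag-search configuration
#'
#' @param min_lag,max_lag search range in seconds (default 0 to 30).
#' @param step grid step in seconds; `NULL` means one analysis-rate sample.
#' @return object of class `lag_config`.
#' @export
lag_config <- function(min_lag = 0, max_lag = 30, step = NULL) {
  stopifnot(min_lag >= 0, max_lag > min_lag, is.null(step) || step > 0)
  structure(list(min_lag = min_lag, max_lag = max_lag, step = step),
            class = "lag_config")
}

#' tCCA configuration
#'
#' @param rho_threshold canonical-correlation selection threshold (0.3).
#' @param prefilter_cutoff low-pass cutoff (Hz) applied to the physiology
#'   signals at their native rate before embedding (0.5 Hz).
#' @param embed_lags temporal-embedding lag grid in seconds; `NULL` means
#'   0..30 s at one analysis-rate sample.
#' @param max_components cap on the number of returned components.
#' @param ridge ridge regularization added to both covariance blocks (the
#'   embedded copies are highly collinear).
#' @param validate how to estimate the selection correlation: `"split"`
#'   (default) fits the canonical weights on the first half of the recording
#'   and evaluates the correlation on the second half, guarding against the
#'   overfitting inherent to ~100 embedded regressors; `"insample"` thresholds
#'   the in-sample canonical correlations directly.
#' @return object of class `tcca_config`.
#' @export
tcca_config <- function(rho_threshold = 0.3, prefilter_cutoff = 0.5,
                        embed_lags = NULL, max_components = Inf,
                        ridge = 1e-8, validate = c("split", "insample")) {
  stopifnot(rho_threshold > 0, rho_threshold < 1, prefilter_cutoff > 0,
            is.null(embed_lags) || all(embed_lags >= 0), ridge >= 0)
  structure(list(rho_threshold = rho_threshold,
                 prefilter_cutoff = prefilter_cutoff,
                 embed_lags = embed_lags, max_components = max_components,
                 ridge = ridge, validate = match.arg(validate)),
            class = "tcca_config")
}

#' Condition physiology signals onto the fNIRS analysis time axis
#'
#' The GSR signal is low-pass filtered at 5 Hz at its native rate first; every
#' signal is then anti-alias decimated (block means to an intermediate ~10 Hz
#' rate followed by a low-pass at 80% of the target Nyquist), linearly
#' interpolated onto the target time axis, and z-scored. No other filtering is
#' applied.
#'
#' @param record a `physio_record` (list with `signals` time x 6 matrix and
#'   `sample_rate`), covering the fNIRS time span.
#' @param target_times fNIRS analysis time axis (s), uniformly spaced.
#' @param gsr_lowpass GSR low-pass cutoff (Hz).
#' @param prefilter optional low-pass cutoff (Hz) applied to every signal at
#'   the native rate (used by the tCCA path; `NULL` otherwise).
#' @return matrix `length(target_times) x 6` of z-scored regressors (columns
#'   [PHYSIO_SIGNALS]), class `conditioned_regressors`, with an `applied_lag`
#'   attribute of zeros.
#' @export
condition_physio <- function(record, target_times, gsr_lowpass = 5,
                             prefilter = NULL) {
  sig <- record$signals
  pr <- record$sample_rate
  stopifnot(is.matrix(sig), ncol(sig) == length(PHYSIO_SIGNALS))
  colnames(sig) <- PHYSIO_SIGNALS
  t_nat <- (seq_len(nrow(sig)) - 1) / pr
  span <- max(target_times)
  if (t_nat[length(t_nat)] < span - 1e-9)
    stop(sprintf(paste0("physiology record (%.1f s) shorter than the fNIRS ",
                        "span (%.1f s); overlap deficit %.1f s"),
                 t_nat[length(t_nat)], span, span - t_nat[length(t_nat)]))
  fs_t <- 1 / stats::median(diff(target_times))
  if (!is.null(gsr_lowpass) && gsr_lowpass < pr / 2)
    sig[, "gsr"] <- bw_filtfilt(sig[, "gsr"], pr, gsr_lowpass, "low", 4)
  if (!is.null(prefilter)) {
    for (s in PHYSIO_SIGNALS)
      if (prefilter < pr / 2)
        sig[, s] <- bw_filtfilt(sig[, s], pr, prefilter, "low", 4)
  }
  out <- matrix(NA_real_, length(target_times), length(PHYSIO_SIGNALS),
                dimnames = list(NULL, PHYSIO_SIGNALS))
  for (s in PHYSIO_SIGNALS) {
    x <- sig[, s]
    fs <- pr
    t_x <- t_nat
    dec <- floor(fs / 10)
    if (dec >= 2) {                       # stage 1: block means to ~10 Hz
      nb <- floor(length(x) / dec)
      x <- colMeans(matrix(x[seq_len(nb * dec)], nrow = dec))
      fs <- fs / dec
      t_x <- (seq_len(nb) - 1) / fs + (dec - 1) / (2 * pr)
    }
    cutoff <- 0.8 * fs_t / 2              # stage 2: anti-alias low-pass
    if (cutoff < fs / 2) x <- bw_filtfilt(x, fs, cutoff, "low", 4)
    y <- interp1(t_x, x, xout = target_times)
    out[, s] <- zscore(y)
  }
  structure(out, applied_lag = setNames(rep(0, ncol(out)), PHYSIO_SIGNALS),
            class = c("conditioned_regressors", "matrix", "array"))
}

#' Cross-correlation lag optimization for one regressor/channel pair
#'
#' Evaluates the Pearson correlation between the channel and the regressor
#' delayed by each candidate lag on the overlapping support, and returns the
#' lag maximizing the (signed, by default) correlation. Ties break toward the
#' smaller lag.
#'
#' @param regressor conditioned regressor series.
#' @param channel hemoglobin series of equal length and rate.
#' @param fs sampling rate (Hz) shared by both series.
#' @param cfg a [lag_config()].
#' @param use_abs maximize `|r|` instead of signed `r`.
#' @return list with `lag` (s), `correlation` at that lag, and `by_lag`
#'   (data frame of the full grid).
#' @export
find_optimal_lag <- function(regressor, channel, fs, cfg = lag_config(),
                             use_abs = FALSE) {
  stopifnot(length(regressor) == length(channel), fs > 0)
  if (stats::sd(regressor) == 0 || stats::sd(channel) == 0)
    stop("correlation undefined: constant regressor or channel")
  step <- cfg$step %||% (1 / fs)
  lags <- seq(cfg$min_lag, cfg$max_lag, by = step)
  n <- length(regressor)
  r <- vapply(lags, function(lag) {
    k <- as.integer(ceiling(lag * fs - 1e-9))
    if (k >= n - 2) return(NA_real_)
    x <- shift_series(regressor, lag, fs)
    stats::cor(x[(k + 1):n], channel[(k + 1):n])
  }, numeric(1))
  score <- if (use_abs) abs(r) else r
  best <- which.max(score)               # which.max: first max -> smaller lag
  list(lag = lags[best], correlation = r[best],
       by_lag = data.frame(lag = lags, correlation = r))
}

# Lag matrix for all channels x signals (vectorized over the lag grid).
optimal_lag_matrix <- function(regressors, Y, fs, cfg = lag_config()) {
  step <- cfg$step %||% (1 / fs)
  lags <- seq(cfg$min_lag, cfg$max_lag, by = step)
  n <- nrow(Y)
  best_r <- matrix(-Inf, ncol(Y), ncol(regressors))
  best_lag <- matrix(cfg$min_lag, ncol(Y), ncol(regressors))
  for (lag in lags) {
    k <- as.integer(ceiling(lag * fs - 1e-9))
    if (k >= n - 2) next
    Xl <- apply(regressors, 2, shift_series, lag_s = lag, fs = fs)
    r <- stats::cor(Y[(k + 1):n, , drop = FALSE],
                    Xl[(k + 1):n, , drop = FALSE])
    upd <- r > best_r
    best_r[upd] <- r[upd]
    best_lag[upd] <- lag
  }
  dimnames(best_lag) <- dimnames(best_r) <-
    list(colnames(Y), colnames(regressors))
  list(lags = best_lag, correlations = best_r)
}

# Temporal embedding: delayed copies of each column at the given lag grid.
embed_lagged <- function(X, lags_s, fs) {
  cols <- lapply(colnames(X), function(s) {
    m <- vapply(lags_s, function(l) shift_series(X[, s], l, fs),
                numeric(nrow(X)))
    colnames(m) <- sprintf("%s_lag%05.2f", s, lags_s)
    m
  })
  do.call(cbind, cols)
}

#' Ridge-regularized canonical correlation analysis
#'
#' Solves the CCA generalized eigenproblem on z-scored matrices with a ridge
#' term on both covariance blocks. Canonical correlations are returned in
#' decreasing order, clamped to \[0, 1\].
#'
#' @param X,Y numeric matrices with equal row counts.
#' @param ridge ridge added to the diagonal of both covariance blocks
#'   (relative to unit variances).
#' @return list with `rho` (canonical correlations), `wx` (X-side weights,
#'   columns normalized to unit-variance variates), `xcenter`, `xscale`,
#'   `ycenter`, `yscale`, and `condition_number` of the X covariance block.
#' @export
cca_fit <- function(X, Y, ridge = 1e-8) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) > 2)
  n <- nrow(X)
  xc <- colMeans(X); yc <- colMeans(Y)
  xs <- apply(X, 2, stats::sd); ys <- apply(Y, 2, stats::sd)
  if (any(xs == 0) || any(ys == 0)) stop("constant column in CCA input")
  Xs <- scale(X, xc, xs); Ys <- scale(Y, yc, ys)
  Cxx <- crossprod(Xs) / (n - 1) + ridge * diag(ncol(X))
  Cyy <- crossprod(Ys) / (n - 1) + ridge * diag(ncol(Y))
  Cxy <- crossprod(Xs, Ys) / (n - 1)
  ev_x <- eigen(Cxx, symmetric = TRUE, only.values = TRUE)$values
  cond_num <- max(ev_x) / max(min(ev_x), .Machine$double.eps)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  eig <- eigen(M)
  vals <- Re(eig$values)
  ord <- order(vals, decreasing = TRUE)
  k <- min(ncol(X), ncol(Y))
  ord <- ord[seq_len(k)]
  rho <- sqrt(pmin(pmax(vals[ord], 0), 1))
  wx <- Re(eig$vectors[, ord, drop = FALSE])
  # y-side weights from the stationarity condition wy ~ Cyy^-1 Cyx wx
  wy <- solve(Cyy, t(Cxy) %*% wx)
  # normalize weights so each in-sample variate has unit variance
  norm_w <- function(W, Z) {
    sdu <- apply(Z %*% W, 2, stats::sd)
    sdu[sdu == 0] <- 1
    sweep(W, 2, sdu, `/`)
  }
  wx <- norm_w(wx, Xs)
  wy <- norm_w(wy, Ys)
  list(rho = rho, wx = wx, wy = wy, xcenter = xc, xscale = xs,
       ycenter = yc, yscale = ys, condition_number = cond_num)
}

#' tCCA: select latent physiological components correlated with fNIRS
#'
#' Physiology signals are low-pass filtered at the configured cutoff (0.5 Hz)
#' at their native rate, conditioned onto the analysis time axis, temporally
#' embedded (delayed copies at the embedding lag grid, 0-30 s by default), and
#' canonically correlated with the multichannel fNIRS matrix (all long
#' channels, both chromophores). Components whose selection correlation meets
#' `rho_threshold` (0.3) are returned as nuisance regressors.
#'
#' With `validate = "split"` (default) the selection correlation is evaluated
#' out-of-sample: weights are fit on the first half of the recording and the
#' canonical correlation is measured on the second half, which keeps spurious
#' components from the ~100 highly collinear embedded regressors out of the
#' design.
#'
#' @param record a `physio_record`.
#' @param hemo analysis-rate `hemo_ts` (long channels are used).
#' @param target_times analysis time axis (s).
#' @param cfg a [tcca_config()].
#' @return list with `components` (matrix `n x k` of selected physiology-side
#'   variates, possibly 0 columns), `rho` (in-sample canonical correlations,
#'   decreasing), `rho_select` (correlations used for selection), `selected`
#'   (logical), `n_selected`, and `condition_number`.
#' @export
tcca_select_components <- function(record, hemo, target_times,
                                   cfg = tcca_config()) {
  fs <- 1 / stats::median(diff(target_times))
  regs <- condition_physio(record, target_times,
                           prefilter = cfg$prefilter_cutoff)
  lags <- cfg$embed_lags %||% seq(0, 30, by = 1 / fs)
  Xe <- embed_lagged(unclass(regs), lags, fs)
  long <- !hemo$channels$is_short
  Yl <- rbind_chroma(hemo, long)
  if (nrow(Yl) != nrow(Xe)) stop("fNIRS series and time axis disagree")
  max_k <- as.integer(ceiling(max(lags) * fs))
  rows <- (max_k + 1):nrow(Xe)           # interior support (edges held)
  fit_all <- cca_fit(Xe[rows, ], Yl[rows, ], cfg$ridge)
  if (cfg$validate == "split") {
    half <- seq_len(floor(length(rows) / 2))
    r1 <- rows[half]; r2 <- rows[-half]
    fit1 <- cca_fit(Xe[r1, ], Yl[r1, ], cfg$ridge)
    U2 <- scale(Xe[r2, ], fit1$xcenter, fit1$xscale) %*% fit1$wx
    V2 <- scale(Yl[r2, ], fit1$ycenter, fit1$yscale) %*% fit1$wy
    rho_sel <- vapply(seq_along(fit1$rho), function(k) {
      if (stats::sd(U2[, k]) == 0 || stats::sd(V2[, k]) == 0) return(0)
      stats::cor(U2[, k], V2[, k])
    }, numeric(1))
    wx <- fit1$wx
    centers <- fit1$xcenter; scales <- fit1$xscale
    rho_in <- fit1$rho
  } else {
    rho_sel <- fit_all$rho
    wx <- fit_all$wx
    centers <- fit_all$xcenter; scales <- fit_all$xscale
    rho_in <- fit_all$rho
  }
  selected <- rho_sel >= cfg$rho_threshold
  if (is.finite(cfg$max_components) && sum(selected) > cfg$max_components) {
    keep_k <- order(rho_sel, decreasing = TRUE)[seq_len(cfg$max_components)]
    selected <- seq_along(selected) %in% keep_k & selected
  }
  comps <- scale(Xe, centers, scales) %*% wx[, selected, drop = FALSE]
  if (ncol(comps) > 0)
    colnames(comps) <- sprintf("tcca_%02d", which(selected))
  list(components = comps, rho = rho_in, rho_select = rho_sel,
       selected = selected, n_selected = sum(selected),
       condition_number = fit_all$condition_number)
}

# Long-channel fNIRS matrix with both chromophores side by side (time x 2C).
rbind_chroma <- function(hemo, which_ch) {
  idx <- which(which_ch)
  hbo <- t(hemo$conc[idx, 1, , drop = FALSE][, 1, ])
  hbr <- t(hemo$conc[idx, 2, , drop = FALSE][, 1, ])
  out <- cbind(hbo, hbr)
  colnames(out) <- c(paste0(hemo$channels$channel[idx], "_hbo"),
                     paste0(hemo$channels$channel[idx], "_hbr"))
  out
}
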