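# Small, fast simulation configuration for unit tests (desk scale: fewer
# channels and trials, shorter sessions, 50 Hz physiology).
small_cfg <- function(...) {
  defaults <- list(n_sessions = 3, n_long_channels = 6, n_short_channels = 2,
                   session_duration = 420, n_trials_per_condition = 5,
                   physio_rate = 50, superficial_gain = 1, noise_sd = 0.2,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Noise-free configuration with a single physiology coupling.
coupling_cfg <- function(signal = "heart_rate", gain = 1, lag_s = 10, ...) {
  cp <- default_physio_couplings()
  cp$gain <- 0
  cp$gain[cp$signal == signal] <- gain
  cp$lag_s[cp$signal == signal] <- lag_s
  small_cfg(noise_sd = 0, superficial_gain = 0,
            true_betas = c(left_ifg = 0, right_ifg = 0,
                           left_auditory_primary = 0,
                           left_auditory_secondary = 0,
                           right_auditory_primary = 0,
                           right_auditory_secondary = 0),
            physio_couplings = cp, ...)
}

# Minimal hemo_ts from a time x channel HbO matrix (HbR = -1/3 HbO).
toy_hemo <- function(hbo, fs = 0.6, n_short = 0, short_hbo = NULL) {
  n_long <- ncol(hbo)
  n <- nrow(hbo)
  chan <- make_toy_channels(n_long, n_short)
  conc <- array(0, dim = c(n_long + n_short, 2, n))
  for (j in seq_len(n_long)) {
    conc[j, 1, ] <- hbo[, j]
    conc[j, 2, ] <- -hbo[, j] / 3
  }
  if (n_short > 0) for (j in seq_len(n_short)) {
    conc[n_long + j, 1, ] <- short_hbo[, j]
    conc[n_long + j, 2, ] <- -short_hbo[, j] / 3
  }
  hemo_ts(conc, fs, chan)
}

make_toy_channels <- function(n_long, n_short = 0) {
  data.frame(
    channel = c(sprintf("L%02d", seq_len(n_long)),
                if (n_short > 0) sprintf("S%02d", seq_len(n_short))),
    source = seq_len(n_long + n_short), detector = seq_len(n_long + n_short),
    separation_mm = c(rep(30, n_long), rep(8, n_short)),
    is_short = c(rep(FALSE, n_long), rep(TRUE, n_short)),
    roi = c(rep(ROI_LABELS, length.out = n_long), rep(NA, n_short)),
    stringsAsFactors = FALSE)
}

# Band-limited noise helper for constructing analysis-rate series.
slow_noise <- function(n, fs = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  flt <- signal::butter(2, min(0.9, 0.25 * 2 / fs), type = "low")
  x <- signal::filtfilt(flt, x)
  as.numeric(x / stats::sd(x))
}
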