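# Synthetic multi-session SPA-fNIRS data generator with known ground truth.
#
# Emulates the study conditions of a ~20-min passive auditory block design:
# 20 speech trials (5.18-7.31 s, mean 6.1 s) and 20 silence trials (6 s),
# 15-30 s inter-stimulus intervals, dual-wavelength intensities at 5.1 Hz for
# 38 long (30 mm) + 8 short (8 mm) channels, six peripheral physiology signals
# at 500 Hz coupled into long channels at known lags, a superficial hemodynamic
# component shared between long and short channels, and 10 sessions with
# session-to-session amplitude variability.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 10 sessions of ~20 min at 5.1 Hz,
#' 38 long + 8 short channels over six regions of interest, 20 speech trials
#' (5.18-7.31 s, mean 6.1 s) and 20 six-second silence trials with 15-30 s
#' inter-stimulus intervals, six physiology signals sampled at 500 Hz and
#' coupled into long channels at signal-specific lags, and a 0.01-0.5 Hz
#' superficial component common to long and short channels.
#'
#' @param n_sessions number of recording sessions.
#' @param n_long_channels,n_short_channels long (30 mm) and short (8 mm)
#'   source-detector channel counts.
#' @param sample_rate_raw fNIRS sampling rate (Hz).
#' @param physio_rate physiology sampling rate (Hz).
#' @param session_duration recording length (s).
#' @param n_trials_per_condition trials per condition (speech, control).
#' @param stim_duration_range speech-trial duration range (s); must lie inside
#'   \[5.18, 7.31\].
#' @param stim_duration_mean mean speech-trial duration (s); durations are
#'   drawn from a scaled Beta distribution on `stim_duration_range` with this
#'   mean.
#' @param control_duration silence-trial duration (s).
#' @param isi_range inter-stimulus interval range (s); must lie inside
#'   \[15, 30\].
#' @param hrf_params canonical HRF shape parameters (see [canonical_hrf()]).
#' @param true_betas named vector of true speech HbO peak amplitudes (uM) per
#'   ROI (names from [ROI_LABELS]); zeros mark inactive regions. Evoked HbR is
#'   -1/3 of HbO. The control condition evokes no response.
#' @param session_beta_sd SD (uM) of the additive session-level shift applied
#'   to active-ROI speech betas (shared across ROIs within a session).
#' @param physio_couplings data frame with columns `signal`, `gain` (uM per
#'   z-unit) and `lag_s`: each z-scored physiology signal enters every long
#'   channel delayed by `lag_s`.
#' @param superficial_gain SD (uM) of the superficial component in HbO;
#'   per-channel gains jitter uniformly within +/-20%.
#' @param noise_sd SD (uM) of white measurement noise on long/short HbO
#'   (HbR noise is one third).
#' @param intensity_noise_sd multiplicative intensity noise SD (unitless);
#'   0 disables it (wavelengths then share all structure and the scalp
#'   coupling index is ~1 for every channel).
#' @param seed integer seed; fully determines the generated dataset.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 10,
                       n_long_channels = 38,
                       n_short_channels = 8,
                       sample_rate_raw = 5.1,
                       physio_rate = 500,
                       session_duration = 1200,
                       n_trials_per_condition = 20,
                       stim_duration_range = c(5.18, 7.31),
                       stim_duration_mean = 6.1,
                       control_duration = 6,
                       isi_range = c(15, 30),
                       hrf_params = list(peak = 6, undershoot = 16, ratio = 6),
                       true_betas = c(left_ifg = 0, right_ifg = 0,
                                      left_auditory_primary = 1,
                                      left_auditory_secondary = 1,
                                      right_auditory_primary = 1,
                                      right_auditory_secondary = 1),
                       session_beta_sd = 0.5,
                       physio_couplings = default_physio_couplings(),
                       superficial_gain = 2,
                       noise_sd = 0.3,
                       intensity_noise_sd = 0,
                       seed = 1L) {
  cfg <- list(n_sessions = n_sessions, n_long_channels = n_long_channels,
              n_short_channels = n_short_channels,
              sample_rate_raw = sample_rate_raw, physio_rate = physio_rate,
              session_duration = session_duration,
              n_trials_per_condition = n_trials_per_condition,
              stim_duration_range = stim_duration_range,
              stim_duration_mean = stim_duration_mean,
              control_duration = control_duration, isi_range = isi_range,
              hrf_params = hrf_params, true_betas = true_betas,
              session_beta_sd = session_beta_sd,
              physio_couplings = physio_couplings,
              superficial_gain = superficial_gain, noise_sd = noise_sd,
              intensity_noise_sd = intensity_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_sessions >= 1, n_long_channels >= 1, n_short_channels >= 0,
              sample_rate_raw > 0, physio_rate > 0, session_duration > 0,
              n_trials_per_condition >= 1, control_duration > 0,
              session_beta_sd >= 0, superficial_gain >= 0, noise_sd >= 0,
              intensity_noise_sd >= 0)
    if (stim_duration_range[1] < 5.18 - 1e-9 ||
        stim_duration_range[2] > 7.31 + 1e-9 ||
        stim_duration_range[1] > stim_duration_range[2])
      stop("stim_duration_range must lie within [5.18, 7.31]")
    if (isi_range[1] < 15 - 1e-9 || isi_range[2] > 30 + 1e-9 ||
        isi_range[1] > isi_range[2])
      stop("isi_range must lie within [15, 30]")
    if (stim_duration_mean < stim_duration_range[1] ||
        stim_duration_mean > stim_duration_range[2])
      stop("stim_duration_mean must lie inside stim_duration_range")
    if (!all(names(true_betas) %in% ROI_LABELS))
      stop("true_betas names must be ROI labels")
    stopifnot(is.data.frame(physio_couplings),
              all(c("signal", "gain", "lag_s") %in% names(physio_couplings)),
              all(physio_couplings$signal %in% PHYSIO_SIGNALS),
              all(is.finite(physio_couplings$gain)),
              all(physio_couplings$lag_s >= 0 & physio_couplings$lag_s <= 30))
  })
  invisible(cfg)
}

#' Default physiology-to-channel couplings
#'
#' One coupling per peripheral signal: gain 0.2 uM per z-unit, with lags set to
#' the per-signal transit times observed in single-subject auditory recordings
#' (heart rate 5.50 s, respiration 28.17 s, SpO2 18.83 s, PPG 0.67 s,
#' GSR 20.83 s, temperature 10.00 s).
#'
#' @return data frame with columns `signal`, `gain`, `lag_s`.
#' @export
default_physio_couplings <- function() {
  data.frame(signal = PHYSIO_SIGNALS,
             gain = 0.2,
             lag_s = c(5.50, 28.17, 18.83, 0.67, 20.83, 10.00))
}

# Speech-trial durations: scaled Beta on the configured range with the
# configured mean (shape1 = 2; shape2 solved from the mean).
draw_speech_durations <- function(n, range, mean_s) {
  m <- (mean_s - range[1]) / (range[2] - range[1])
  a <- 2
  b <- a * (1 - m) / m
  range[1] + (range[2] - range[1]) * stats::rbeta(n, a, b)
}

#' Generate a randomized block-design event schedule
#'
#' Speech and control trials are interleaved in random order with uniform
#' inter-stimulus intervals. Draws are rejected until the schedule (plus a
#' 10 s lead-in and a 16 s tail so every -1..+15 s epoch fits the recording)
#' fits the session duration.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `onset`, `duration`, `condition`
#'   (`"speech"`/`"control"`), onsets strictly increasing.
#' @export
generate_schedule <- function(config) {
  n_per <- config$n_trials_per_condition
  n_tot <- 2L * n_per
  lead_in <- 10
  tail_s <- 16
  min_total <- lead_in +
    n_per * config$stim_duration_range[1] + n_per * config$control_duration +
    n_tot * config$isi_range[1] + tail_s
  if (min_total > config$session_duration)
    stop("schedule infeasible: ", n_tot, " trials with minimum ISI need ",
         round(min_total, 1), " s but session_duration is ",
         config$session_duration, " s", call. = FALSE)
  for (try in seq_len(500L)) {
    cond <- sample(rep(c("speech", "control"), each = n_per))
    dur <- ifelse(cond == "speech",
                  draw_speech_durations(n_tot, config$stim_duration_range,
                                        config$stim_duration_mean),
                  config$control_duration)
    isi <- stats::runif(n_tot, config$isi_range[1], config$isi_range[2])
    onsets <- lead_in + cumsum(c(0, (dur + isi)[-n_tot]))
    if (onsets[n_tot] + dur[n_tot] + tail_s <= config$session_duration)
      return(data.frame(onset = onsets, duration = dur, condition = cond))
  }
  stop("schedule infeasible: could not place all trials within ",
       config$session_duration, " s after 500 attempts", call. = FALSE)
}

# Channel/montage table: long channels assigned round-robin to the six ROIs.
make_channel_table <- function(n_long, n_short) {
  roi <- rep(ROI_LABELS, length.out = n_long)
  roi <- roi[order(match(roi, ROI_LABELS))]
  data.frame(
    channel = c(sprintf("L%02d", seq_len(n_long)),
                if (n_short > 0) sprintf("S%02d", seq_len(n_short))),
    source = seq_len(n_long + n_short),
    detector = c(seq_len(n_long), seq_len(max(n_short, 0))),
    separation_mm = c(rep(30, n_long), rep(8, n_short)),
    is_short = c(rep(FALSE, n_long), rep(TRUE, n_short)),
    roi = c(roi, rep(NA_character_, n_short)),
    stringsAsFactors = FALSE
  )
}

# Stimulus-locked drive at a coarse rate: unit-peak gamma kernel placed at
# speech onsets, optionally delayed; used to shape autonomic reactions.
stim_drive <- function(t_coarse, onsets, fs, delay = 0, width = 4) {
  n <- length(t_coarse)
  x <- numeric(n)
  idx <- round((onsets + delay) * fs) + 1L
  idx <- idx[idx >= 1 & idx <= n]
  x[idx] <- 1
  tk <- seq(0, 20, by = 1 / fs)
  k <- stats::dgamma(tk, shape = 3, rate = 3 / width)
  k <- k / max(k)
  fft_conv(x, k)[seq_len(n)]
}

smooth_noise <- function(n, fs, cutoff = 0.05, sd = 1) {
  x <- bw_filtfilt(stats::rnorm(n), fs, cutoff, "low", order = 2)
  sd * x / stats::sd(x)
}

#' Generate one session's peripheral physiology record
#'
#' Waveform models: heart rate ~1 bpm-scale slow oscillation with a
#' stimulus-locked dip; respiration ~15 brpm with slow drift; SpO2 ~98% with a
#' delayed stimulus-locked rise; PPG = cardiac-band oscillation with amplitude
#' modulation that increases after speech onsets; GSR = smoothed random walk
#' with delayed stimulus-locked rises; temperature = slow drift. Slow
#' components are synthesized at 10 Hz and interpolated to the native rate.
#'
#' @param config a [sim_config()].
#' @param schedule event schedule from [generate_schedule()].
#' @return object of class `physio_record`: list with `signals` (time x 6
#'   matrix, columns [PHYSIO_SIGNALS]) and `sample_rate`.
#' @export
generate_physio <- function(config, schedule) {
  pr <- config$physio_rate
  dur <- config$session_duration
  n <- round(dur * pr)
  t_full <- (seq_len(n) - 1) / pr
  fs_c <- 10
  nc <- round(dur * fs_c)
  tc <- (seq_len(nc) - 1) / fs_c
  sp_on <- schedule$onset[schedule$condition == "speech"]

  drive0 <- stim_drive(tc, sp_on, fs_c, delay = 0, width = 4)
  drive4 <- stim_drive(tc, sp_on, fs_c, delay = 4, width = 8)
  drive2 <- stim_drive(tc, sp_on, fs_c, delay = 2, width = 6)

  hr_c <- 62 + 2.5 * sin(2 * pi * 0.012 * tc + stats::runif(1, 0, 2 * pi)) +
    smooth_noise(nc, fs_c, 0.03, 1) - 1.5 * drive0
  resp_c <- 15 + 1.2 * sin(2 * pi * 0.006 * tc + stats::runif(1, 0, 2 * pi)) +
    smooth_noise(nc, fs_c, 0.02, 0.4)
  spo2_c <- 98 + smooth_noise(nc, fs_c, 0.01, 0.25) + 0.4 * drive4
  gsr_c <- 2 + 0.5 * smooth_noise(nc, fs_c, 0.02, 1) + 0.8 * drive2
  temp_c <- 33.2 + smooth_noise(nc, fs_c, 0.005, 0.15)

  plan <- interp_plan(nc, fs_c, t_full)
  interp <- function(xc) interp_apply(xc, plan)
  signals <- matrix(NA_real_, n, length(PHYSIO_SIGNALS),
                    dimnames = list(NULL, PHYSIO_SIGNALS))
  signals[, "heart_rate"] <- interp(hr_c)
  signals[, "respiration"] <- interp(resp_c)
  signals[, "spo2"] <- interp(spo2_c)
  signals[, "gsr"] <- interp(gsr_c)
  signals[, "temperature"] <- interp(temp_c)
  # PPG: cardiac oscillation whose instantaneous frequency follows heart rate
  # and whose amplitude rises after speech onsets.
  phase <- 2 * pi * cumsum(signals[, "heart_rate"] / 60) / pr
  amp <- 1 + 0.25 * interp(drive0) + 0.1 * interp(smooth_noise(nc, fs_c, 0.05))
  signals[, "ppg"] <- amp * sin(phase)
  structure(list(signals = signals, sample_rate = pr),
            class = "physio_record")
}

#' Generate one synthetic recording session
#'
#' Long channels receive the HRF-convolved evoked signal (active ROIs only),
#' the superficial component, lagged physiology couplings and white noise;
#' short channels receive only the superficial component and noise. Hemoglobin
#' concentrations are encoded to dual-wavelength intensities with the modified
#' Beer-Lambert forward model so the preprocessing chain can invert them.
#'
#' @param config a [sim_config()].
#' @param session_index 1-based session number (`<= n_sessions`); offsets the
#'   seed so sessions are independent but reproducible.
#' @param beta_shift additive session-level shift (uM) applied to active-ROI
#'   speech betas (drawn by [generate_dataset()]).
#' @return object of class `fnirs_session`: list with elements `scan`
#'   ([raw_scan()]), `physio`, `events`, `truth` (realized betas, injected
#'   lags, superficial series, z-scored injected physiology at the fNIRS rate)
#'   and `session`.
#' @export
generate_session <- function(config, session_index = 1L, beta_shift = 0) {
  validate_sim_config(config)
  if (session_index < 1 || session_index > config$n_sessions)
    stop("session_index must be in 1..n_sessions")
  set.seed(config$seed + 9973L * as.integer(session_index))

  schedule <- generate_schedule(config)
  physio <- generate_physio(config, schedule)

  fs <- config$sample_rate_raw
  n <- round(config$session_duration * fs)
  t_f <- (seq_len(n) - 1) / fs
  chan <- make_channel_table(config$n_long_channels, config$n_short_channels)
  n_long <- config$n_long_channels
  n_short <- config$n_short_channels

  # Stimulus regressors (unit-peak HRF x 3 s boxcar kernel).
  sp <- event_regressor(schedule$onset[schedule$condition == "speech"], n, fs,
                        config$hrf_params)
  ct <- event_regressor(schedule$onset[schedule$condition == "control"], n, fs,
                        config$hrf_params)

  # Realized speech betas: session shift applied to active ROIs only.
  beta_roi <- setNames(rep(0, length(ROI_LABELS)), ROI_LABELS)
  beta_roi[names(config$true_betas)] <- config$true_betas
  active <- beta_roi != 0
  beta_roi[active] <- beta_roi[active] + beta_shift

  # Superficial component (unit SD) and per-channel gains.
  superficial <- if (config$superficial_gain > 0) band_noise(n, fs)
                 else numeric(n)
  gains <- config$superficial_gain *
    stats::runif(n_long + n_short, 0.8, 1.2)

  # Lagged physiology couplings, z-scored at native physiology rate and
  # interpolated onto the fNIRS time axis before shifting.
  z_inj <- matrix(0, n, length(PHYSIO_SIGNALS),
                  dimnames = list(NULL, PHYSIO_SIGNALS))
  zplan <- interp_plan(nrow(physio$signals), physio$sample_rate, t_f)
  for (s in PHYSIO_SIGNALS)
    z_inj[, s] <- interp_apply(zscore(physio$signals[, s]), zplan)
  coupling <- numeric(n)
  cp <- config$physio_couplings
  if (nrow(cp) > 0 && any(cp$gain != 0)) {
    coupling <- rowSums(vapply(seq_len(nrow(cp)), function(i) {
      cp$gain[i] * shift_series(z_inj[, cp$signal[i]], cp$lag_s[i], fs)
    }, numeric(n)))
  }

  hbo <- matrix(0, n, n_long + n_short)
  hbr <- matrix(0, n, n_long + n_short)
  beta_chan <- data.frame(channel = chan$channel, roi = chan$roi,
                          beta_speech_hbo = 0, beta_control_hbo = 0,
                          stringsAsFactors = FALSE)
  for (c_i in seq_len(n_long + n_short)) {
    if (chan$is_short[c_i]) {
      structured <- gains[c_i] * superficial
    } else {
      b <- beta_roi[chan$roi[c_i]]
      beta_chan$beta_speech_hbo[c_i] <- b
      structured <- b * sp + gains[c_i] * superficial + coupling
    }
    hbo[, c_i] <- structured +
      if (config$noise_sd > 0) stats::rnorm(n, sd = config$noise_sd) else 0
    hbr[, c_i] <- -structured / 3 +
      if (config$noise_sd > 0) stats::rnorm(n, sd = config$noise_sd / 3) else 0
  }

  # Modified Beer-Lambert forward model to dual-wavelength intensities.
  E <- extinction_coefficients(c(760, 850))
  intens <- array(NA_real_, dim = c(n_long + n_short, 2L, n),
                  dimnames = list(chan$channel, c("760", "850"), NULL))
  ppf <- 0.1
  for (c_i in seq_len(n_long + n_short)) {
    dod <- (E %*% rbind(hbo[, c_i], hbr[, c_i])) *
      (chan$separation_mm[c_i] * ppf)
    I <- exp(-dod)
    if (config$intensity_noise_sd > 0)
      I <- I * exp(matrix(stats::rnorm(2L * n,
                                       sd = config$intensity_noise_sd),
                          2L, n))
    intens[c_i, , ] <- I
  }

  scan <- raw_scan(intens, fs, chan, wavelengths = c(760, 850))
  truth <- structure(list(
    beta_roi_speech_hbo = beta_roi,
    beta_shift = beta_shift,
    channel_betas = beta_chan,
    lags = setNames(cp$lag_s, cp$signal),
    coupling_gains = setNames(cp$gain, cp$signal),
    superficial = superficial,
    superficial_gains = setNames(gains, chan$channel),
    physio_injected = z_inj,
    hbr_ratio = -1 / 3
  ), class = "ground_truth")

  structure(list(scan = scan, physio = physio, events = schedule,
                 truth = truth, session = as.integer(session_index)),
            class = "fnirs_session")
}

#' Generate a full multi-session dataset
#'
#' Draws one session-level beta shift per session (SD `session_beta_sd`,
#' shared across active ROIs within a session) and generates each session
#' independently. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param sessions if `FALSE`, skip the (expensive) per-session signal
#'   synthesis and return only the realized ground-truth betas — useful for
#'   checking the session-variability model.
#' @return object of class `fnirs_dataset`: list with `sessions` (list of
#'   [generate_session()] bundles, or `NULL`), `realized_betas` (session x ROI
#'   matrix of speech HbO betas), `beta_shifts`, and `config`.
#' @export
generate_dataset <- function(config, sessions = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  shifts <- stats::rnorm(config$n_sessions, 0, config$session_beta_sd)
  beta_roi <- setNames(rep(0, length(ROI_LABELS)), ROI_LABELS)
  beta_roi[names(config$true_betas)] <- config$true_betas
  realized <- t(vapply(shifts, function(d) {
    b <- beta_roi
    b[b != 0] <- b[b != 0] + d
    b
  }, beta_roi))
  rownames(realized) <- sprintf("session%02d", seq_len(config$n_sessions))
  bundles <- NULL
  if (sessions)
    bundles <- lapply(seq_len(config$n_sessions), function(s)
      generate_session(config, s, beta_shift = shifts[s]))
  structure(list(sessions = bundles, realized_betas = realized,
                 beta_shifts = shifts, config = config),
            class = "fnirs_dataset")
}
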