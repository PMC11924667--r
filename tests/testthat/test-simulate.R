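# Synthetic multi-session generator: schedules, determinism, signal content.

test_that("default schedule places 20 speech and 20 silence trials with the stated timing", {
  set.seed(1)
  sch <- generate_schedule(sim_config())
  expect_equal(sum(sch$condition == "speech"), 20)
  expect_equal(sum(sch$condition == "control"), 20)
  expect_true(all(diff(sch$onset) > 0))
  sp <- sch$duration[sch$condition == "speech"]
  expect_true(all(sp >= 5.18 & sp <= 7.31))
  expect_true(all(sch$duration[sch$condition == "control"] == 6))
  gaps <- sch$onset[-1] - (sch$onset[-nrow(sch)] + sch$duration[-nrow(sch)])
  expect_true(all(gaps >= 15 - 1e-9 & gaps <= 30 + 1e-9))
})

test_that("speech-trial durations average 6.1 s", {
  set.seed(7)
  durs <- unlist(lapply(1:50, function(i) {
    sch <- generate_schedule(sim_config())
    sch$duration[sch$condition == "speech"]
  }))
  expect_equal(mean(durs), 6.1, tolerance = 0.05 / 6.1)
})

test_that("a session too short for all trials at minimum ISI is rejected", {
  expect_error(generate_schedule(sim_config(session_duration = 300)),
               "infeasible")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  b1 <- generate_session(cfg, 2)
  b2 <- generate_session(cfg, 2)
  expect_identical(b1, b2)
  d1 <- generate_dataset(small_cfg(n_sessions = 2))
  d2 <- generate_dataset(small_cfg(n_sessions = 2))
  expect_identical(d1, d2)
})

test_that("datasets contain n_sessions bundles with the full event count", {
  ds <- generate_dataset(small_cfg(n_sessions = 3))
  expect_length(ds$sessions, 3)
  for (b in ds$sessions)
    expect_equal(nrow(b$events), 10)  # 5 per condition in the test config
  expect_equal(dim(ds$realized_betas), c(3, length(ROI_LABELS)))
})

test_that("with no signal sources the channels are identically zero", {
  cfg <- coupling_cfg(gain = 0)
  b <- generate_session(cfg, 1)
  expect_true(all(b$scan$intensity == b$scan$intensity[1, 1, 1]))
  od <- intensity_to_od(b$scan)
  expect_true(all(od$od == 0))
  hemo <- od_to_hemoglobin(od)
  expect_true(all(hemo$conc == 0))
})

test_that("a single noise-free coupling reproduces the delayed physiology trace", {
  cfg <- coupling_cfg(signal = "heart_rate", gain = 1, lag_s = 10)
  b <- generate_session(cfg, 1)
  hemo <- od_to_hemoglobin(intensity_to_od(b$scan))
  fs <- b$scan$sample_rate
  z <- b$truth$physio_injected[, "heart_rate"]
  k <- as.integer(round(10 * fs))
  expected <- c(rep(z[1], k), z[seq_len(length(z) - k)])
  got <- hemo$conc[1, 1, ]
  expect_equal(got - mean(got), expected - mean(expected), tolerance = 1e-8)
  # short channels carry no coupling
  sidx <- which(hemo$channels$is_short)[1]
  expect_true(all(hemo$conc[sidx, 1, ] == 0))
})

test_that("short channels contain no evoked energy", {
  cfg <- small_cfg(noise_sd = 0.01, superficial_gain = 0,
                   physio_couplings = within(default_physio_couplings(),
                                             gain <- 0))
  b <- generate_session(cfg, 1)
  hemo <- od_to_hemoglobin(intensity_to_od(b$scan))
  fs <- hemo$sample_rate
  n <- dim(hemo$conc)[3]
  sp <- event_regressor(b$events$onset[b$events$condition == "speech"], n, fs)
  X <- cbind(speech = sp, intercept = 1)
  sidx <- which(hemo$channels$is_short)
  fit <- fit_ols(t(hemo$conc[sidx, 1, , drop = FALSE][, 1, ]), X)
  expect_lt(max(abs(fit$beta["speech", ])), 0.05)
  # and an active long channel recovers its beta
  lidx <- which(hemo$channels$roi == "left_auditory_primary")[1]
  fitL <- fit_ols(hemo$conc[lidx, 1, ], X)
  expect_equal(unname(fitL$beta["speech", 1]), 1, tolerance = 0.05)
})

test_that("session-level beta variance matches the configured variance", {
  vars <- vapply(1:200, function(r) {
    cfg <- small_cfg(n_sessions = 10, session_beta_sd = 2, seed = 1000L + r)
    ds <- generate_dataset(cfg, sessions = FALSE)
    var(ds$realized_betas[, "left_auditory_primary"])
  }, numeric(1))
  expect_equal(mean(vars), 4, tolerance = 0.5 / 4)
  # inactive ROIs stay exactly zero
  cfg <- small_cfg(n_sessions = 5, session_beta_sd = 2)
  ds <- generate_dataset(cfg, sessions = FALSE)
  expect_true(all(ds$realized_betas[, "left_ifg"] == 0))
})

test_that("physiology record has six named signals at the native rate", {
  cfg <- small_cfg()
  b <- generate_session(cfg, 1)
  expect_identical(colnames(b$physio$signals), PHYSIO_SIGNALS)
  expect_equal(b$physio$sample_rate, cfg$physio_rate)
  expect_equal(nrow(b$physio$signals),
               round(cfg$session_duration * cfg$physio_rate))
  expect_true(all(is.finite(b$physio$signals)))
  expect_true(all(b$physio$signals[, "respiration"] > 0))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(stim_duration_range = c(5, 7.31)), "5.18")
  expect_error(sim_config(isi_range = c(10, 30)), "isi_range")
  cp <- default_physio_couplings()
  cp$lag_s[1] <- 40
  expect_error(sim_config(physio_couplings = cp))
  expect_error(generate_session(small_cfg(), 99), "session_index")
})
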