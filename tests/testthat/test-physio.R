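# Physiology conditioning, lag optimization, and temporally embedded CCA.

toy_record <- function(signals, rate) {
  colnames(signals) <- PHYSIO_SIGNALS
  structure(list(signals = signals, sample_rate = rate),
            class = "physio_record")
}

analysis_times <- function(duration, fs = 0.6) seq(0, duration, by = 1 / fs)

test_that("conditioned regressors are z-scored on the analysis axis", {
  set.seed(31)
  dur <- 420
  rate <- 50
  sig <- matrix(rnorm(dur * rate * 6, mean = 50, sd = 5), ncol = 6)
  t_out <- analysis_times(dur - 5)
  regs <- condition_physio(toy_record(sig, rate), t_out)
  expect_equal(nrow(regs), length(t_out))
  expect_identical(colnames(regs), PHYSIO_SIGNALS)
  expect_true(all(abs(colMeans(regs)) < 1e-6))
  expect_true(all(abs(apply(regs, 2, sd) - 1) < 1e-6))
  # physiology shorter than the fNIRS span errors with an overlap report
  expect_error(condition_physio(toy_record(sig, rate),
                                analysis_times(dur + 60)),
               "overlap")
})

test_that("the GSR low-pass attenuates 10 Hz by more than 20 dB", {
  fs <- 100
  t <- (0:9999) / fs
  x <- sin(2 * pi * 0.2 * t) + sin(2 * pi * 10 * t)
  y <- zero_phase_lowpass(x, fs, 5)
  amp <- function(v, f0) {
    sp <- Mod(fft(v - mean(v)))
    fr <- (seq_along(v) - 1) * fs / length(v)
    max(sp[abs(fr - f0) < 0.05])
  }
  expect_lt(amp(y, 10) / amp(x, 10), 10^(-20 / 20))
  expect_equal(amp(y, 0.2) / amp(x, 0.2), 1, tolerance = 0.02)
})

test_that("lag search returns the true delay and stays on the grid", {
  fs <- 0.6
  n <- 720
  x <- slow_noise(n, fs, seed = 32)
  cfg <- lag_config()
  # exact delayed copy: 10 s = 6 analysis samples
  ch <- c(rep(x[1], 6), x[1:(n - 6)])
  res <- find_optimal_lag(x, ch, fs, cfg)
  expect_equal(res$lag, 10, tolerance = 1e-9)
  expect_equal(res$correlation, 1, tolerance = 1e-12)
  # no delay: the self-correlation peaks at zero
  expect_equal(find_optimal_lag(x, x, fs, cfg)$lag, 0)
  # grid bounds hold for arbitrary channels
  for (i in 1:10) {
    ch_i <- slow_noise(n, fs, seed = 100 + i)
    lag_i <- find_optimal_lag(x, ch_i, fs, cfg)$lag
    expect_true(lag_i >= 0 && lag_i <= 30)
  }
  expect_error(find_optimal_lag(rep(1, n), ch, fs, cfg), "constant")
})

test_that("lag search equals an independently coded brute-force loop", {
  fs <- 1
  n <- 300
  cfg <- lag_config(min_lag = 0, max_lag = 20, step = 1)
  lags_grid <- seq(0, 20, by = 1)
  for (i in 1:25) {
    reg <- slow_noise(n, fs, seed = 200 + i)
    ch <- slow_noise(n, fs, seed = 300 + i) + 0.5 * reg
    got <- find_optimal_lag(reg, ch, fs, cfg)
    want <- lag_oracle(reg, ch, fs, lags_grid)
    expect_equal(got$lag, want$lag)
    expect_equal(got$correlation, want$correlation, tolerance = 1e-10)
  }
})

test_that("per-channel lag matrix agrees with the scalar search", {
  fs <- 0.6
  n <- 400
  set.seed(33)
  regs <- cbind(a = slow_noise(n, fs, 41), b = slow_noise(n, fs, 42))
  Y <- cbind(c1 = c(rep(regs[1, 1], 3), regs[1:(n - 3), 1]),
             c2 = regs[, 2] + 0.1 * slow_noise(n, fs, 43))
  lm_res <- spafnirs:::optimal_lag_matrix(regs, Y, fs, lag_config())
  for (ci in 1:2) for (si in 1:2) {
    one <- find_optimal_lag(regs[, si], Y[, ci], fs, lag_config())
    expect_equal(lm_res$lags[ci, si], one$lag)
    expect_equal(lm_res$correlations[ci, si], one$correlation,
                 tolerance = 1e-10)
  }
})

test_that("ridge CCA with a single zero lag reduces to ordinary CCA", {
  set.seed(34)
  X <- matrix(rnorm(300 * 3), ncol = 3)
  Y <- matrix(rnorm(300 * 4), ncol = 4)
  Y[, 1] <- Y[, 1] + 0.8 * X[, 1]
  fit <- cca_fit(X, Y, ridge = 1e-10)
  ref <- stats::cancor(scale(X), scale(Y))
  expect_equal(fit$rho, ref$cor, tolerance = 1e-6)
  expect_true(all(diff(fit$rho) <= 1e-12))
  expect_true(all(fit$rho >= 0 & fit$rho <= 1))
})

test_that("tCCA detects an exactly coupled physiology signal", {
  fs_p <- 10
  dur <- 1230
  t_p <- seq(0, dur, by = 1 / fs_p)
  set.seed(35)
  base <- vapply(1:6, function(i) slow_noise(length(t_p), fs_p, 400 + i),
                 numeric(length(t_p)))
  t_out <- analysis_times(1199, 0.6)
  # channel 1 = heart-rate trace delayed by 5 s (three analysis samples)
  hr_an <- approx(t_p, base[, 1], xout = t_out - 5, rule = 2)$y
  hbo <- cbind(hr_an,
               vapply(2:4, function(i) slow_noise(length(t_out), 0.6, 500 + i),
                      numeric(length(t_out))))
  hemo <- toy_hemo(hbo, fs = 0.6)
  tc <- tcca_select_components(toy_record(base, fs_p), hemo, t_out)
  expect_gte(tc$n_selected, 1)
  expect_gt(max(tc$rho_select), 0.95)
  expect_gt(tc$rho[1], 0.95)
  expect_equal(nrow(tc$components), length(t_out))

  # selected components correlate with the coupled channel
  expect_gt(abs(cor(tc$components[, 1], hbo[, 1])), 0.8)
})

test_that("independent physiology yields no components above threshold", {
  fs_p <- 10
  t_out <- analysis_times(1199, 0.6)
  hits <- vapply(1:20, function(r) {
    set.seed(600 + r)
    base <- matrix(rnorm(12301 * 6), ncol = 6)
    hbo <- vapply(1:4, function(i) rnorm(length(t_out)),
                  numeric(length(t_out)))
    tc <- tcca_select_components(toy_record(base, fs_p), toy_hemo(hbo),
                                 t_out)
    tc$n_selected > 0
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})
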