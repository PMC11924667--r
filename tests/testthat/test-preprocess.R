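# Preprocessing chain: OD, SCI pruning, TDDR, MBLL, filtering/resampling,
# short-channel subtraction.

# periodogram amplitude of the component nearest f0
spectral_amp <- function(x, fs, f0) {
  n <- length(x)
  sp <- stats::fft(x - mean(x))
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  2 * max(Mod(sp[half][abs(freqs[half] - f0) < 0.02])) / n
}

make_scan <- function(I_mat, fs = 5, short = FALSE) {
  # I_mat: time x wavelength for one channel
  intens <- array(NA_real_, dim = c(1, 2, nrow(I_mat)))
  intens[1, 1, ] <- I_mat[, 1]
  intens[1, 2, ] <- I_mat[, 2]
  raw_scan(intens, fs, make_toy_channels(if (short) 0 else 1,
                                         if (short) 1 else 0))
}

test_that("optical density conversion matches the analytic definition", {
  I <- cbind(rep(2, 10), rep(5, 10))
  od <- intensity_to_od(make_scan(I))
  expect_true(all(od$od == 0))

  # one sample at 0.4x the others lies at half the channel mean -> OD = ln 2
  x <- c(rep(1, 2), 0.4)
  expect_equal(mean(x) / 2, x[3])
  od <- intensity_to_od(make_scan(cbind(x, x)))
  expect_equal(od$od[1, 1, 3], log(2), tolerance = 1e-12)

  set.seed(3)
  I <- cbind(runif(50, 0.5, 2), runif(50, 0.5, 2))
  od <- intensity_to_od(make_scan(I))
  for (w in 1:2)
    expect_equal(od$od[1, w, ], -log(I[, w] / mean(I[, w])), tolerance = 1e-12)

  I[7, 1] <- 0
  expect_error(intensity_to_od(make_scan(I)), "L01")
})

test_that("scalp coupling index is the filtered inter-wavelength correlation", {
  fs <- 5.1
  n <- 2000
  set.seed(4)
  shared <- sin(2 * pi * 1.4 * (0:(n - 1)) / fs)
  a <- shared + rnorm(n, sd = 0.5)
  b <- shared + rnorm(n, sd = 0.5)
  scan <- make_scan(exp(-cbind(a, b) * 0.01), fs = fs)
  od <- intensity_to_od(scan)
  sci <- scalp_coupling_index(od)

  # oracle: same FIR taps applied causally with stats::filter, delay removed
  h <- signal::fir1(ceiling(3.3 * fs / 0.1) + ceiling(3.3 * fs / 0.1) %% 2,
                    1.35 * 2 / fs, type = "high")
  L <- length(h)
  d <- (L - 1) / 2
  filt <- function(x) {
    xp <- c(rep(0, L), x, rep(0, L))
    y <- stats::filter(xp, h, method = "convolution", sides = 1)
    as.numeric(y[(L + d + 1):(L + d + length(x))])
  }
  r_expected <- cor(filt(od$od[1, 1, ]), filt(od$od[1, 2, ]))
  expect_equal(sci$sci[1], r_expected, tolerance = 1e-6)

  # identical wavelengths: SCI = 1, kept; sign-flipped: SCI = -1, dropped
  x <- rnorm(n)
  same <- intensity_to_od(make_scan(exp(-cbind(x, x) * 0.01), fs = fs))
  flip <- intensity_to_od(make_scan(exp(-cbind(x, -x) * 0.01), fs = fs))
  expect_equal(scalp_coupling_index(same)$sci[1], 1, tolerance = 1e-6)
  expect_true(scalp_coupling_index(same)$keep[1])
  expect_equal(scalp_coupling_index(flip)$sci[1], -1, tolerance = 1e-6)
  expect_false(scalp_coupling_index(flip)$keep[1])

  # too-short series for the FIR order
  short_od <- intensity_to_od(make_scan(exp(-cbind(x[1:50], x[1:50])), fs = fs))
  expect_error(scalp_coupling_index(short_od), "too short")
})

test_that("pruned channels never appear downstream", {
  cfg <- small_cfg()
  b <- generate_session(cfg, 1)
  od <- intensity_to_od(b$scan)
  keep <- rep(TRUE, nrow(od$channels))
  keep[2] <- FALSE
  dropped_name <- od$channels$channel[2]
  od2 <- prune_channels(od, keep)
  expect_false(dropped_name %in% od2$channels$channel)
  expect_equal(dim(od2$od)[1], sum(keep))
  hemo <- od_to_hemoglobin(od2)
  expect_false(dropped_name %in% hemo$channels$channel)
  expect_identical(attr(od2, "dropped"), dropped_name)
  expect_error(prune_channels(od, rep(FALSE, nrow(od$channels))),
               "every channel")
})

test_that("TDDR matches an independent transcription and suppresses steps", {
  fs <- 5
  t <- (0:1499) / fs
  smooth <- 0.5 * sin(2 * pi * 0.1 * t)
  # nothing to repair: deviation bounded by the mild biweight shrinkage
  expect_lt(max(abs(tddr(smooth, fs) - smooth)), 0.15 * 0.5)
  expect_identical(tddr(rep(0, 100), fs), rep(0, 100))

  set.seed(9)
  x <- smooth + rnorm(length(t), sd = 0.05)
  step <- c(rep(0, 750), rep(10 * sd(x), 750))
  y <- x + step
  fixed <- tddr(y, fs)
  expect_equal(fixed, tddr_oracle(y, fs), tolerance = 1e-9)
  jump_before <- abs(mean(y[751:1500]) - mean(y[1:750]))
  jump_after <- abs(mean(fixed[751:1500]) - mean(fixed[1:750]))
  expect_lt(jump_after, 0.2 * jump_before)
  expect_length(fixed, length(y))
})

test_that("modified Beer-Lambert inversion round-trips the forward model", {
  E <- extinction_coefficients(c(760, 850))
  set.seed(11)
  hbo <- rnorm(10)
  hbr <- rnorm(10)
  d <- 30
  ppf <- 0.1
  od_mat <- E %*% rbind(hbo, hbr) * d * ppf
  # build the OD object directly (bypasses the mean-referencing step)
  od <- structure(list(od = array(0, dim = c(1, 2, 10)), sample_rate = 5,
                       channels = make_toy_channels(1),
                       wavelengths = c(760, 850)), class = "od_series")
  od$od[1, 1, ] <- od_mat[1, ]
  od$od[1, 2, ] <- od_mat[2, ]
  hemo <- od_to_hemoglobin(od)
  expect_equal(hemo$conc[1, 1, ], hbo, tolerance = 1e-10)
  expect_equal(hemo$conc[1, 2, ], hbr, tolerance = 1e-10)

  # hand-coded 2x2 solve oracle on one time point
  sol <- solve(E, od_mat[, 4] / (d * ppf))
  expect_equal(unname(hemo$conc[1, , 4]), unname(sol), tolerance = 1e-10)

  # doubling the partial pathlength factor halves the concentrations
  hemo2 <- od_to_hemoglobin(od, preprocess_config(ppf = 0.2))
  expect_equal(hemo2$conc, hemo$conc / 2, tolerance = 1e-12)

  expect_true(all(od_to_hemoglobin(structure(
    list(od = array(0, dim = c(1, 2, 5)), sample_rate = 5,
         channels = make_toy_channels(1), wavelengths = c(760, 850)),
    class = "od_series"))$conc == 0))
  expect_error(extinction_coefficients(c(760, 760)), "distinct")
})

test_that("bandpass and resample honor rates and the passband", {
  fs <- 5.1
  n <- 6120
  t <- (0:(n - 1)) / fs
  x <- 5 + sin(2 * pi * 0.1 * t)
  hemo <- toy_hemo(matrix(x, ncol = 1), fs = fs)

  out <- bandpass_and_resample(hemo, band = NULL, target_rate = 0.6)
  expect_equal(out$sample_rate, 0.6)
  expect_equal(dim(out$conc)[3], length(seq(0, t[n], by = 1 / 0.6)))
  # 0.1 Hz passes the anti-aliased decimation: spectral amplitude within 5%
  y <- out$conc[1, 1, ]
  amp <- spectral_amp(y, 0.6, 0.1)
  expect_equal(amp, 1, tolerance = 0.05)

  bp <- bandpass_and_resample(hemo, band = c(0.02, 0.4), target_rate = NULL)
  expect_lt(abs(mean(bp$conc[1, 1, ])), 0.05)  # DC (5 uM) outside passband
  amp_bp <- spectral_amp(bp$conc[1, 1, ], fs, 0.1)
  expect_equal(amp_bp, 1, tolerance = 0.05)

  expect_error(bandpass_and_resample(hemo, band = c(0.02, 0.4),
                                     target_rate = 0.6), "Nyquist")
  expect_error(bandpass_and_resample(hemo, target_rate = 10), "below")
})

test_that("short-channel subtraction is the least-squares projection", {
  set.seed(13)
  n <- 500
  ref <- slow_noise(n, 5)
  evoked <- slow_noise(n, 5, seed = 99)
  hemo <- toy_hemo(cbind(2 * ref, ref + evoked), fs = 5, n_short = 1,
                   short_hbo = matrix(ref, ncol = 1))
  out <- short_channel_subtract(hemo)
  # long channel 1 is an exact scaling of the reference -> residual 0
  expect_lt(max(abs(out$conc[1, 1, ])), 1e-10)
  # residual orthogonal to the reference
  expect_lt(abs(sum(out$conc[2, 1, ] * ref)), 1e-8 * n)
  # projection oracle: residual = evoked minus its projection on the ref
  proj <- evoked - ref * sum(evoked * ref) / sum(ref^2)
  expect_equal(out$conc[2, 1, ], ref + evoked -
                 ref * sum((ref + evoked) * ref) / sum(ref^2),
               tolerance = 1e-10)
  expect_equal(out$conc[2, 1, ], proj, tolerance = 1e-10)
  # short channels untouched
  expect_equal(out$conc[3, 1, ], ref)

  no_short <- toy_hemo(cbind(ref), fs = 5)
  expect_warning(out2 <- short_channel_subtract(no_short), "no short")
  expect_identical(out2$conc, no_short$conc)
})

test_that("the GLM input is the resampled MBLL output, bit for bit", {
  b <- generate_session(small_cfg(), 1)
  pp <- preprocess_for_glm(b$scan)
  od <- intensity_to_od(b$scan)
  sci <- scalp_coupling_index(od)
  manual <- bandpass_and_resample(
    od_to_hemoglobin(prune_channels(od, sci$keep)),
    band = NULL, target_rate = 0.6)
  expect_identical(pp$hemo$conc, manual$conc)
})
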