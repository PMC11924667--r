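# Design matrices, OLS fitting, ROI aggregation, significance, RMSE
# comparisons.

toy_events <- function() {
  data.frame(onset = c(15, 60, 105, 150),
             duration = c(6, 6, 6, 6),
             condition = c("speech", "control", "speech", "control"))
}

test_that("design matrices have the model-specific column sets", {
  n <- 200
  fs <- 0.6
  ev <- toy_events()
  set.seed(41)
  physio <- matrix(rnorm(n * 6), ncol = 6,
                   dimnames = list(NULL, PHYSIO_SIGNALS))
  short <- cbind(ss_hbo = rnorm(n), ss_hbr = rnorm(n))
  tcca <- matrix(rnorm(n * 2), ncol = 2,
                 dimnames = list(NULL, c("tcca_01", "tcca_02")))
  lags <- matrix(5, nrow = 3, ncol = 6,
                 dimnames = list(c("L01", "L02", "L03"), PHYSIO_SIGNALS))

  d_none <- build_design_matrix("none", ev, n, fs)
  expect_equal(ncol(d_none$X), 3)
  expect_setequal(colnames(d_none$X), c("speech", "control", "intercept"))

  d_ph <- build_design_matrix("physio", ev, n, fs, physio = physio)
  expect_equal(ncol(d_ph$X), ncol(d_none$X) + 6)

  d_ss <- build_design_matrix("ss", ev, n, fs, short = short)
  expect_equal(ncol(d_ss$X), 5)

  d_both <- build_design_matrix("ss_physio", ev, n, fs, physio = physio,
                                short = short)
  expect_equal(ncol(d_both$X), 11)

  d_tcca <- build_design_matrix("ss_tcca", ev, n, fs, short = short,
                                tcca = tcca)
  expect_equal(ncol(d_tcca$X), 7)

  d_lag <- build_design_matrix("ss_physio_lag", ev, n, fs, physio = physio,
                               short = short, lags = lags)
  expect_equal(ncol(d_lag$X), 5)
  expect_length(d_lag$per_channel, 3)
  expect_equal(ncol(d_lag$per_channel[[1]]), 6)

  expect_error(build_design_matrix("ss", ev, n, fs, short = NULL),
               "short channels")
})

test_that("the stimulus regressor is the HRF convolved with a 3 s boxcar", {
  fs <- 2
  n <- 150
  onset <- 10
  x <- event_regressor(onset, n, fs)
  # direct convolution oracle
  th <- seq(0, 32, by = 1 / fs)
  h <- canonical_hrf(th)
  box <- rep(1, round(3 * fs))
  k <- rep(0, length(h) + length(box) - 1)
  for (i in seq_along(h)) for (j in seq_along(box))
    k[i + j - 1] <- k[i + j - 1] + h[i] * box[j]
  k <- k / max(k)
  want <- rep(0, n)
  i0 <- round(onset * fs) + 1
  idx <- i0:min(n, i0 + length(k) - 1)
  want[idx] <- k[seq_along(idx)]
  expect_equal(x, want, tolerance = 1e-10)
  expect_equal(max(x), 1, tolerance = 1e-12)
})

test_that("OLS fit matches the normal-equations oracle", {
  set.seed(42)
  for (i in 1:10) {
    n <- 50
    X <- cbind(1, matrix(rnorm(n * 3), ncol = 3))
    colnames(X) <- c("intercept", "a", "b", "c")
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    want <- ols_oracle(X, y)
    expect_equal(unname(fit$beta[, 1]), want$beta, tolerance = 1e-10)
    expect_equal(unname(fit$se[, 1]), want$se, tolerance = 1e-10)
    expect_equal(unname(fit$rmse[1]), want$rmse, tolerance = 1e-10)
    expect_equal(unname(fit$rmse[1]^2 * n), sum((y - X %*% want$beta)^2),
                 tolerance = 1e-8)
  }
})

test_that("a noiseless identifiable system is recovered exactly", {
  ev <- toy_events()
  d <- build_design_matrix("none", ev, 200, 0.6)
  beta_true <- c(speech = 2, control = -0.5, intercept = 1)
  y <- d$X %*% beta_true
  fit <- fit_ols(y, d)
  expect_equal(fit$beta[, 1], beta_true, tolerance = 1e-10)
  expect_lt(fit$rmse[1], 1e-10)
})

test_that("a nuisance column orthogonal to the data leaves betas unchanged", {
  set.seed(43)
  ev <- toy_events()
  d <- build_design_matrix("none", ev, 200, 0.6)
  y <- d$X %*% c(1.5, 0.2, 0.4) + rnorm(200, sd = 0.3)
  z <- rnorm(200)
  z <- residuals(lm(z ~ cbind(d$X, y) - 1))  # orthogonal to X and y
  X2 <- cbind(d$X, nuis = z)
  expect_equal(unname(fit_ols(y, X2)$beta["speech", 1]),
               unname(fit_ols(y, d)$beta["speech", 1]), tolerance = 1e-10)
})

test_that("nested models never increase the residual sum of squares", {
  set.seed(44)
  n <- 300
  ev <- toy_events()
  physio <- matrix(rnorm(n * 6), ncol = 6,
                   dimnames = list(NULL, PHYSIO_SIGNALS))
  short <- cbind(ss_hbo = rnorm(n), ss_hbr = rnorm(n))
  y <- rnorm(n)
  rss <- vapply(list(
    build_design_matrix("none", ev, n, 0.6),
    build_design_matrix("ss", ev, n, 0.6, short = short),
    build_design_matrix("ss_physio", ev, n, 0.6, short = short,
                        physio = physio)),
    function(d) fit_ols(y, d)$rss[1], numeric(1))
  expect_true(rss[2] <= rss[1] + 1e-12)
  expect_true(rss[3] <= rss[2] + 1e-12)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  set.seed(45)
  x <- rnorm(50)
  X <- cbind(intercept = 1, a = x, b = 2 * x)
  expect_error(fit_ols(rnorm(50), X), "collinear")
})

test_that("ROI aggregation uses inverse-standard-error weights", {
  expect_equal(unname(roi_weighted_average(c(2, 4), c(1, 2), c("r", "r"))),
               8 / 3)
  expect_equal(unname(roi_weighted_average(c(1, 3), c(2, 2), c("r", "r"))),
               2)  # equal SE -> arithmetic mean
  expect_equal(unname(roi_weighted_average(5, 0.1, "solo")), 5)
})

test_that("one-sample beta tests behave at the corrected alpha", {
  expect_false(test_betas(rep(0, 10))$significant)
  x <- c(0.8, 1.2, 1.1, 0.9, 1.0)
  tt <- test_betas(x)
  expect_equal(tt$t, mean(x) / (sd(x) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(abs(tt$t), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  zv <- test_betas(rep(2, 6))
  expect_true(zv$significant)
  expect_lt(zv$p, .Machine$double.eps)
  expect_error(test_betas(1), "at least 2")
})

test_that("pairwise RMSE comparisons cover all model pairs", {
  set.seed(46)
  d <- expand.grid(session = 1:8, model = CORRECTION_MODELS)
  d$rmse <- rnorm(nrow(d), mean = 1, sd = 0.05)
  cmp <- compare_model_rmse(d)
  expect_equal(nrow(cmp), choose(6, 2))
  same <- data.frame(session = rep(1:5, 2),
                     model = rep(c("none", "ss"), each = 5),
                     rmse = rep(runif(5), 2))
  cs <- compare_model_rmse(same)
  expect_equal(cs$mean_diff, 0)
  expect_false(cs$significant)
  expect_error(compare_model_rmse(d[d$session == 1, ]), "two sessions")
})
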