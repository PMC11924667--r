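# Independent brute-force oracles used to cross-check the implementation.

# OLS via explicit normal equations.
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  rss <- sum(res^2)
  dof <- nrow(X) - ncol(X)
  se <- sqrt(diag(xtx_inv) * rss / dof)
  list(beta = as.numeric(beta), se = as.numeric(se),
       rmse = sqrt(rss / nrow(X)))
}

# ICC(3,k) via a two-way ANOVA fit with aov().
icc_oracle <- function(mat) {
  d <- data.frame(rating = as.vector(mat),
                  target = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                  rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  a <- summary(stats::aov(rating ~ target + rater, data = d))[[1]]
  bms <- a["target", "Mean Sq"]
  ems <- a["Residuals", "Mean Sq"]
  (bms - ems) / bms
}

# Exhaustive lag search with an independently coded correlation loop.
lag_oracle <- function(reg, ch, fs, lags) {
  best <- NULL
  best_r <- -Inf
  for (lag in lags) {
    k <- as.integer(round(lag * fs))
    if (k >= length(reg) - 2) next
    a <- if (k == 0) reg else c(rep(reg[1], k), reg[seq_len(length(reg) - k)])
    r <- cor(a[(k + 1):length(reg)], ch[(k + 1):length(ch)])
    if (r > best_r) {
      best_r <- r
      best <- lag
    }
  }
  list(lag = best, correlation = best_r)
}

# Independent transcription of the TDDR algorithm (explicit loops).
tddr_oracle <- function(x, fs) {
  if (stats::sd(x) == 0) return(x)
  m0 <- mean(x)
  y <- x - m0
  if (fs > 1) {
    flt <- signal::butter(3, 0.5 * 2 / fs, type = "low")
    y_low <- signal::filtfilt(flt, y)
  } else y_low <- y
  y_high <- y - y_low
  dv <- diff(y_low)
  w <- rep(1, length(dv))
  mu <- Inf
  iter <- 0
  while (iter < 50) {
    iter <- iter + 1
    mu0 <- mu
    mu <- sum(w * dv) / sum(w)
    dev <- dv - mu
    sigma <- 1.4826 * median(abs(dev))
    if (sigma == 0) break
    r <- dev / (sigma * 4.685)
    w <- ((1 - r^2) * (abs(r) < 1))^2
    if (is.finite(mu0) && abs(mu - mu0) <= 1e-9 * max(abs(mu), abs(mu0), 1))
      break
  }
  yc <- cumsum(c(0, w * (dv - mu)))
  yc <- yc - mean(yc)
  yc + y_high + m0
}
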