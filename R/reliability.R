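# ICC(3,k) test-retest reliability (sessions = targets, ROIs = raters,
# speech-condition betas = ratings) and per-ROI session variances.

ICC_BANDS <- c(poor = 0.40, fair = 0.60, good = 0.75, excellent = 1.00)

#' Reliability band for an ICC value
#'
#' Left-closed intervals: poor `< 0.40`, fair `[0.40, 0.60)`, good
#' `[0.60, 0.75)`, excellent `[0.75, 1.00]`.
#'
#' @param icc numeric ICC value(s).
#' @return character band label(s); `NA` input maps to `NA`.
#' @export
icc_band <- function(icc) {
  vapply(icc, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0.40) "poor"
    else if (v < 0.60) "fair"
    else if (v < 0.75) "good"
    else "excellent"
  }, character(1))
}

#' ICC(3,k): two-way mixed effects, consistency, average of k raters
#'
#' Two-way ANOVA decomposition of the ratings matrix (targets x raters):
#' `ICC(3,k) = (BMS - EMS) / BMS`, with BMS the between-targets mean square
#' and EMS the residual mean square (Shrout-Fleiss consistency for the average
#' of k raters). Rows with any missing rating are dropped (and counted).
#'
#' @param ratings numeric matrix, rows = targets (sessions), columns = raters
#'   (ROIs); at least 2 x 2 after dropping incomplete rows.
#' @return object of class `reliability_result`: list with `icc`, `band`,
#'   `F`, `df1`, `df2`, `p`, mean squares (`bms`, `jms`, `ems`), `n_targets`,
#'   `k_raters`, `n_dropped_rows`. When the between-target variance is zero,
#'   `icc` is `NA` with a diagnostic message.
#' @export
icc_3k <- function(ratings) {
  stopifnot(is.matrix(ratings))
  complete <- stats::complete.cases(ratings)
  n_dropped <- sum(!complete)
  ratings <- ratings[complete, , drop = FALSE]
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("ratings matrix must be at least 2 targets x 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  jms <- ss_cols / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (bms <= 0) {
    res <- list(icc = NA_real_, band = NA_character_, F = NA_real_,
                df1 = n - 1, df2 = (n - 1) * (k - 1), p = NA_real_,
                bms = bms, jms = jms, ems = ems, n_targets = n, k_raters = k,
                n_dropped_rows = n_dropped,
                message = "zero between-target variance; ICC undefined")
    return(structure(res, class = "reliability_result"))
  }
  icc <- (bms - ems) / bms
  Fv <- bms / ems
  p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, band = icc_band(icc), F = Fv, df1 = n - 1,
                 df2 = (n - 1) * (k - 1), p = p, bms = bms, jms = jms,
                 ems = ems, n_targets = n, k_raters = k,
                 n_dropped_rows = n_dropped, message = NULL),
            class = "reliability_result")
}

#' Sample variance of session-level betas
#'
#' Sample variance (n - 1 denominator) of the per-session ROI beta estimates.
#'
#' @param betas numeric vector of session-level betas (length >= 2).
#' @return the sample variance.
#' @export
session_variance <- function(betas) {
  betas <- betas[!is.na(betas)]
  if (length(betas) < 2) stop("need at least 2 sessions for a variance")
  stats::var(betas)
}
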