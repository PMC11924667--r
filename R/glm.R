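# Design-matrix construction for the six correction models, OLS GLM fitting,
# ROI aggregation, significance testing, and model RMSE comparison.

#' Build the design matrix for one correction model
#'
#' Stimulus columns are the canonical double-gamma HRF convolved with a 3 s
#' boxcar placed at speech and control onsets; an intercept is always
#' included. Model-specific nuisance columns:
#' \describe{
#'   \item{none}{no nuisance regressors}
#'   \item{physio}{the six conditioned physiology signals}
#'   \item{ss}{short-channel means, one column per chromophore}
#'   \item{ss_physio}{union of `ss` and `physio`}
#'   \item{ss_physio_lag}{short-channel means plus per-channel lag-optimized
#'     physiology (channel-specific columns)}
#'   \item{ss_tcca}{short-channel means plus selected tCCA components}
#' }
#' No drift/polynomial regressors are included, consistent with fitting the
#' unfiltered signal.
#'
#' @param model one of [CORRECTION_MODELS].
#' @param schedule event schedule (`onset`, `duration`, `condition`).
#' @param n number of analysis samples.
#' @param fs analysis sampling rate (Hz).
#' @param hrf_params canonical HRF parameters (see [canonical_hrf()]).
#' @param boxcar_width stimulus boxcar width (s), default 3.
#' @param physio conditioned physiology matrix `n x 6` (models containing
#'   `physio`).
#' @param short short-channel mean matrix `n x 2` with columns `ss_hbo`,
#'   `ss_hbr` (models containing `ss`); an error is raised when required but
#'   absent (no surviving short channels).
#' @param tcca tCCA component matrix `n x k` (model `ss_tcca`; `k = 0` allowed).
#' @param lags per-channel lag matrix `channels x 6` in seconds (model
#'   `ss_physio_lag`).
#' @return object of class `design_matrix`: list with `X` (common columns),
#'   `per_channel` (`NULL` or per-channel extra-column matrices), `groups`
#'   (named list of column names: `stimulus`, `intercept`, and the model's
#'   nuisance groups), and `model`.
#' @export
build_design_matrix <- function(model, schedule, n, fs,
                                hrf_params = list(peak = 6, undershoot = 16,
                                                  ratio = 6),
                                boxcar_width = 3,
                                physio = NULL, short = NULL, tcca = NULL,
                                lags = NULL) {
  model <- match.arg(model, CORRECTION_MODELS)
  sp <- event_regressor(schedule$onset[schedule$condition == "speech"], n, fs,
                        hrf_params, boxcar_width)
  ct <- event_regressor(schedule$onset[schedule$condition == "control"], n, fs,
                        hrf_params, boxcar_width)
  X <- cbind(speech = sp, control = ct, intercept = rep(1, n))
  groups <- list(stimulus = c("speech", "control"), intercept = "intercept")
  needs_ss <- model %in% c("ss", "ss_physio", "ss_physio_lag", "ss_tcca")
  needs_physio <- model %in% c("physio", "ss_physio")
  if (needs_ss) {
    if (is.null(short))
      stop("model '", model, "' requires short-channel regressors but no ",
           "short channels survived pruning")
    stopifnot(nrow(short) == n, ncol(short) == 2)
    colnames(short) <- c("ss_hbo", "ss_hbr")
    X <- cbind(X, short)
    groups$ss <- colnames(short)
  }
  if (needs_physio) {
    stopifnot(!is.null(physio), nrow(physio) == n)
    ph <- as.matrix(physio)
    colnames(ph) <- paste0("physio_", colnames(physio) %||% PHYSIO_SIGNALS)
    X <- cbind(X, ph)
    groups$physio <- colnames(ph)
  }
  per_channel <- NULL
  if (model == "ss_physio_lag") {
    stopifnot(!is.null(physio), !is.null(lags))
    ph <- as.matrix(physio)
    sig_names <- colnames(physio) %||% PHYSIO_SIGNALS
    per_channel <- lapply(seq_len(nrow(lags)), function(c_i) {
      m <- vapply(seq_along(sig_names), function(s)
        shift_series(ph[, s], lags[c_i, s], fs), numeric(n))
      colnames(m) <- paste0("lag_physio_", sig_names)
      m
    })
    names(per_channel) <- rownames(lags)
    groups$lag_physio <- paste0("lag_physio_", sig_names)
  }
  if (model == "ss_tcca") {
    stopifnot(!is.null(tcca))
    if (ncol(tcca) > 0) {
      X <- cbind(X, tcca)
      groups$tcca <- colnames(tcca)
    } else {
      groups$tcca <- character(0)
    }
  }
  if (anyDuplicated(colnames(X)))
    stop("duplicate design-matrix column names")
  zero <- apply(X == 0, 2, all)
  if (any(zero))
    stop("all-zero design column(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  structure(list(X = X, per_channel = per_channel, groups = groups,
                 model = model),
            class = "design_matrix")
}

#' Fit an ordinary least squares GLM
#'
#' `beta = (X'X)^-1 X'Y` per response column, standard errors from the
#' diagonal of `sigma^2 (X'X)^-1`, and `rmse = sqrt(RSS / n)`. No temporal
#' filtering, pre-whitening or autocorrelation correction is applied. For
#' designs with per-channel columns (lag model) each response column is fit
#' against its own augmented design.
#'
#' @param Y numeric matrix `n x channels` (or vector).
#' @param design a [build_design_matrix()] result or a plain numeric matrix
#'   with column names.
#' @return object of class `glm_fit`: `beta` and `se` (`regressor x channel`),
#'   `rmse` and `rss` (per channel), `dof`, `groups`, `model`.
#' @export
fit_ols <- function(Y, design) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (is.matrix(design)) design <- list(X = design, per_channel = NULL,
                                        groups = NULL, model = NA_character_)
  X <- design$X
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(Y)
  fit_one_design <- function(Xf, Ym) {
    p <- ncol(Xf)
    qx <- qr(Xf)
    if (qx$rank < p) {
      bad <- colnames(Xf)[qx$pivot[(qx$rank + 1):p]]
      stop("design matrix rank-deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    beta <- qr.coef(qx, Ym)
    res <- Ym - Xf %*% beta
    rss <- colSums(res^2)
    dof <- n - p
    sigma2 <- rss / dof
    d_inv <- numeric(p)
    d_inv[qx$pivot] <- diag(chol2inv(qr.R(qx)))  # (X'X)^-1 diag, unpivoted
    se <- sqrt(outer(d_inv, sigma2))
    dimnames(beta) <- list(colnames(Xf), colnames(Ym))
    dimnames(se) <- dimnames(beta)
    list(beta = beta, se = se, rss = rss, dof = dof)
  }
  if (is.null(design$per_channel)) {
    f <- fit_one_design(X, Y)
    beta <- f$beta; se <- f$se; rss <- f$rss; dof <- f$dof
  } else {
    stopifnot(length(design$per_channel) == ncol(Y))
    p_extra <- ncol(design$per_channel[[1]])
    pn <- c(colnames(X), colnames(design$per_channel[[1]]))
    beta <- matrix(NA_real_, length(pn), ncol(Y),
                   dimnames = list(pn, colnames(Y)))
    se <- beta
    rss <- numeric(ncol(Y))
    for (j in seq_len(ncol(Y))) {
      f <- fit_one_design(cbind(X, design$per_channel[[j]]),
                          Y[, j, drop = FALSE])
      beta[, j] <- f$beta
      se[, j] <- f$se
      rss[j] <- f$rss
      dof <- f$dof
    }
    names(rss) <- colnames(Y)
  }
  structure(list(beta = beta, se = se, rss = rss, rmse = sqrt(rss / n),
                 dof = dof, n = n, groups = design$groups,
                 model = design$model),
            class = "glm_fit")
}

#' Inverse-standard-error-weighted ROI averaging of betas
#'
#' `beta_roi = sum(beta_c / se_c) / sum(1 / se_c)` over the ROI's channels,
#' i.e. weights equal to the inverse of the per-channel standard error.
#'
#' @param beta,se numeric vectors over channels (one regressor).
#' @param roi character vector of ROI labels per channel.
#' @return named numeric vector of per-ROI weighted betas; ROIs with no
#'   channels are `NA` with a warning.
#' @export
roi_weighted_average <- function(beta, se, roi) {
  stopifnot(length(beta) == length(se), length(beta) == length(roi))
  rois <- unique(roi[!is.na(roi)])
  out <- vapply(rois, function(r) {
    i <- which(roi == r)
    if (length(i) == 0) return(NA_real_)
    w <- 1 / se[i]
    sum(beta[i] * w) / sum(w)
  }, numeric(1))
  if (any(is.na(out))) warning("ROI(s) with no surviving channels")
  out
}

#' One-sample t-tests for beta estimates against zero
#'
#' Bonferroni-style fixed alpha (default 0.0025). A zero-variance sample with
#' nonzero mean is flagged significant with `p` reported below machine
#' epsilon.
#'
#' @param betas numeric vector (one test) or matrix `observations x tests`.
#' @param alpha corrected significance level.
#' @return data frame with columns `mean`, `t`, `df`, `p`, `significant`.
#' @export
test_betas <- function(betas, alpha = 0.0025) {
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1)
  n <- nrow(betas)
  if (n < 2) stop("at least 2 observations per test are required")
  m <- colMeans(betas)
  s <- apply(betas, 2, stats::sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)),
                  ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(abs(tstat), n - 1,
                                              lower.tail = FALSE),
              .Machine$double.xmin)
  data.frame(test = colnames(betas) %||% seq_len(ncol(betas)),
             mean = m, t = tstat, df = n - 1, p = p,
             significant = p < alpha, row.names = NULL)
}

#' Pairwise comparison of session-level RMSE between correction models
#'
#' For each pair of models, a paired t-test on the per-session RMSE values
#' with Holm adjustment across the pairs. Requires at least two sessions.
#'
#' @param rmse_df data frame with columns `session`, `model`, `rmse` for one
#'   ROI/chromophore.
#' @return data frame: one row per model pair with `mean_diff` (model_a -
#'   model_b), `t`, `p`, `p_holm`, `significant` (at 0.05 after Holm).
#' @export
compare_model_rmse <- function(rmse_df) {
  stopifnot(all(c("session", "model", "rmse") %in% names(rmse_df)))
  models <- unique(rmse_df$model)
  if (length(models) < 2) stop("need at least two models to compare")
  wide <- do.call(cbind, lapply(models, function(m) {
    d <- rmse_df[rmse_df$model == m, ]
    d$rmse[order(d$session)]
  }))
  colnames(wide) <- models
  if (nrow(wide) < 2) stop("need at least two sessions (paired comparison)")
  pairs <- utils::combn(models, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- wide[, pairs[1, i]]; b <- wide[, pairs[2, i]]
    d <- a - b
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    data.frame(model_a = pairs[1, i], model_b = pairs[2, i],
               mean_diff = mean(d), t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p_holm < 0.05
  out
}
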