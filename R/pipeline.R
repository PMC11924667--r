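# End-to-end orchestration: simulate/load sessions, run the six correction
# models, aggregate to ROIs, and compute across-session statistics (ICC,
# session variances, significance tests, RMSE comparisons, block averages).

#' Pipeline configuration
#'
#' @param input `"synthetic"` (default) or a directory containing one
#'   subdirectory per session written by [write_session_bundle()].
#' @param sim a [sim_config()] (synthetic mode).
#' @param preprocess a [preprocess_config()].
#' @param lag a [lag_config()].
#' @param tcca a [tcca_config()].
#' @param models subset of [CORRECTION_MODELS] to run.
#' @param hrf_params canonical HRF parameters for the design matrices.
#' @param alpha Bonferroni-corrected significance level for beta tests.
#' @param epoch_window block-average epoch window (s).
#' @param block_average run the block-averaging path (epochs, evoked
#'   responses, physiology block averages); disable for beta-only runs.
#' @param denoise compute denoised-signal variance summaries.
#' @param physio_exclusions named list `signal -> integer sessions` to omit
#'   from physiology block averages (e.g. a poorly attached sensor).
#' @param seed overrides `sim$seed` in synthetic mode.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic",
                            sim = sim_config(),
                            preprocess = preprocess_config(),
                            lag = lag_config(),
                            tcca = tcca_config(),
                            models = CORRECTION_MODELS,
                            hrf_params = list(peak = 6, undershoot = 16,
                                              ratio = 6),
                            alpha = 0.0025,
                            epoch_window = c(-1, 15),
                            block_average = TRUE,
                            denoise = TRUE,
                            physio_exclusions = list(),
                            seed = NULL) {
  stopifnot(all(models %in% CORRECTION_MODELS), length(models) >= 1)
  if (identical(input, "synthetic")) {
    if (!is.null(seed)) sim$seed <- as.integer(seed)
  } else if (!dir.exists(input)) {
    stop("input directory does not exist: ", input)
  }
  structure(list(input = input, sim = sim, preprocess = preprocess,
                 lag = lag, tcca = tcca, models = models,
                 hrf_params = hrf_params, alpha = alpha,
                 epoch_window = epoch_window, block_average = block_average,
                 denoise = denoise, physio_exclusions = physio_exclusions),
            class = "pipeline_config")
}

# Short-channel chroma means at the analysis rate (NULL if none survive).
short_channel_means <- function(hemo) {
  short <- hemo$channels$is_short
  if (!any(short)) return(NULL)
  cbind(ss_hbo = apply(hemo$conc[short, 1, , drop = FALSE], 3, mean),
        ss_hbr = apply(hemo$conc[short, 2, , drop = FALSE], 3, mean))
}

# Denoising variants (Eqs. 3-7): groups subtracted and the model whose
# simultaneous fit provides the betas.
DENOISE_VARIANTS <- list(
  physio        = list(model = "ss_physio",     groups = "physio"),
  ss            = list(model = "ss_physio",     groups = "ss"),
  ss_physio     = list(model = "ss_physio",     groups = c("physio", "ss")),
  ss_lag_physio = list(model = "ss_physio_lag", groups = c("lag_physio", "ss")),
  ss_tcca       = list(model = "ss_tcca",       groups = c("tcca", "ss"))
)

process_one_session <- function(bundle, cfg) {
  log <- list()
  pp <- preprocess_for_glm(bundle$scan, cfg$preprocess)
  hemo <- pp$hemo
  if (length(pp$dropped) > 0)
    log <- c(log, list(data.frame(
      session = bundle$session, event = "channel_drop",
      detail = paste0(pp$dropped, " (SCI=",
                      round(pp$sci$sci[!pp$sci$keep], 3), ")"))))
  times <- time_axis(hemo)
  fs <- hemo$sample_rate
  n <- length(times)
  long <- !hemo$channels$is_short
  if (!any(long)) stop("no long channels survived pruning")
  ch_long <- hemo$channels$channel[long]
  roi_long <- hemo$channels$roi[long]
  Y <- list(hbo = t(hemo$conc[long, 1, , drop = FALSE][, 1, ]),
            hbr = t(hemo$conc[long, 2, , drop = FALSE][, 1, ]))
  for (k in CHROMA) colnames(Y[[k]]) <- ch_long
  short_mat <- short_channel_means(hemo)

  need_physio <- any(cfg$models %in% c("physio", "ss_physio",
                                       "ss_physio_lag"))
  regs <- if (need_physio) condition_physio(bundle$physio, times) else NULL

  lag_info <- NULL
  if ("ss_physio_lag" %in% cfg$models) {
    lag_info <- optimal_lag_matrix(unclass(regs), Y$hbo, fs, cfg$lag)
    log <- c(log, list(data.frame(
      session = bundle$session, event = "lag_choice",
      detail = sprintf("%s mean %.2f s", colnames(lag_info$lags),
                       colMeans(lag_info$lags)))))
  }
  tc <- NULL
  if ("ss_tcca" %in% cfg$models) {
    tc <- tcca_select_components(bundle$physio, hemo, times, cfg$tcca)
    log <- c(log, list(data.frame(
      session = bundle$session, event = "tcca_selection",
      detail = sprintf("%d component(s) at rho>=%.2f (cond. number %.1e)",
                       tc$n_selected, cfg$tcca$rho_threshold,
                       tc$condition_number))))
  }

  chan_rows <- list()
  fits <- list()
  designs <- list()
  for (model in cfg$models) {
    design <- build_design_matrix(
      model, bundle$events, n, fs, hrf_params = cfg$hrf_params,
      physio = regs, short = short_mat,
      tcca = if (!is.null(tc)) tc$components else NULL,
      lags = if (!is.null(lag_info)) lag_info$lags else NULL)
    designs[[model]] <- design
    for (k in CHROMA) {
      fit <- fit_ols(Y[[k]], design)
      fits[[model]][[k]] <- fit
      for (cond in c("speech", "control")) {
        chan_rows[[length(chan_rows) + 1L]] <- data.frame(
          session = bundle$session, model = model, chroma = k,
          channel = ch_long, roi = roi_long, condition = cond,
          beta = fit$beta[cond, ], se = fit$se[cond, ], rmse = fit$rmse,
          row.names = NULL)
      }
    }
  }
  channels_df <- do.call(rbind, chan_rows)

  # ROI aggregation: inverse-SE-weighted betas; RMSE averaged over channels.
  roi_rows <- list()
  for (model in cfg$models) for (k in CHROMA) {
    fit <- fits[[model]][[k]]
    rmse_roi <- tapply(fit$rmse, roi_long, mean)
    for (cond in c("speech", "control")) {
      b <- roi_weighted_average(fit$beta[cond, ], fit$se[cond, ], roi_long)
      roi_rows[[length(roi_rows) + 1L]] <- data.frame(
        session = bundle$session, model = model, chroma = k,
        condition = cond, roi = names(b), beta = unname(b),
        rmse = unname(rmse_roi[names(b)]), row.names = NULL)
    }
  }
  roi_df <- do.call(rbind, roi_rows)

  denoise_df <- NULL
  if (isTRUE(cfg$denoise)) {
    dn_rows <- list()
    for (v in names(DENOISE_VARIANTS)) {
      spec_v <- DENOISE_VARIANTS[[v]]
      if (!spec_v$model %in% cfg$models) next
      for (k in CHROMA) {
        dn <- regress_out(Y[[k]], fits[[spec_v$model]][[k]],
                          designs[[spec_v$model]], spec_v$groups)
        dn_rows[[length(dn_rows) + 1L]] <- data.frame(
          session = bundle$session, variant = v, chroma = k,
          var_raw = mean(apply(Y[[k]], 2, stats::var)),
          var_filtered = mean(apply(dn$values, 2, stats::var)))
      }
    }
    denoise_df <- if (length(dn_rows) > 0) do.call(rbind, dn_rows) else NULL
  }

  lag_df <- NULL
  if (!is.null(lag_info)) {
    lag_df <- data.frame(
      session = bundle$session,
      channel = rep(rownames(lag_info$lags), ncol(lag_info$lags)),
      signal = rep(colnames(lag_info$lags), each = nrow(lag_info$lags)),
      lag = as.vector(lag_info$lags),
      correlation = as.vector(lag_info$correlations), row.names = NULL)
  }
  tcca_df <- if (!is.null(tc)) data.frame(
    session = bundle$session, n_selected = tc$n_selected,
    rho_max = if (length(tc$rho) > 0) max(tc$rho) else NA_real_,
    rho_select_max = if (length(tc$rho_select) > 0) max(tc$rho_select)
                     else NA_real_) else NULL

  # Block-averaging path (native rate, bandpassed, SS-subtracted).
  epochs <- NULL
  physio_epochs <- NULL
  if (isTRUE(cfg$block_average)) {
    bp <- preprocess_for_blockavg(bundle$scan, cfg$preprocess)
    bh <- bp$hemo
    bl <- !bh$channels$is_short
    rois <- unique(bh$channels$roi[bl])
    series <- do.call(cbind, lapply(rois, function(r) {
      i <- which(bl & bh$channels$roi == r)
      cbind(apply(bh$conc[i, 1, , drop = FALSE], 3, mean),
            apply(bh$conc[i, 2, , drop = FALSE], 3, mean))
    }))
    colnames(series) <- as.vector(t(outer(rois, CHROMA, paste, sep = "|")))
    epochs <- extract_epochs(series, bh$sample_rate, bundle$events,
                             cfg$epoch_window)
    # Physiology block averages: unfiltered signals interpolated to the
    # native fNIRS axis, plus the pulse-respiration quotient.
    t_nat <- time_axis(bundle$scan)
    t_p <- (seq_len(nrow(bundle$physio$signals)) - 1) /
      bundle$physio$sample_rate
    pmat <- vapply(PHYSIO_SIGNALS, function(s)
      interp1(t_p, bundle$physio$signals[, s], xout = t_nat),
      numeric(length(t_nat)))
    pmat <- cbind(pmat, prq = compute_prq(pmat[, "heart_rate"],
                                          pmat[, "respiration"]))
    physio_epochs <- extract_epochs(pmat, bundle$scan$sample_rate,
                                    bundle$events, cfg$epoch_window)
  }

  list(channels = channels_df, roi = roi_df, denoise = denoise_df,
       lags = lag_df, tcca = tcca_df, epochs = epochs,
       physio_epochs = physio_epochs, n_events = nrow(bundle$events),
       log = if (length(log) > 0) do.call(rbind, log) else NULL)
}

# Pool per-session epoch lists (same window/rate) into one evoked table.
pool_epochs <- function(epoch_list, session_ids, exclusions = list()) {
  conds <- unique(unlist(lapply(epoch_list, names)))
  t_epoch <- attr(epoch_list[[1]], "time")
  series_names <- dimnames(epoch_list[[1]][[conds[1]]])[[3]]
  rows <- list()
  for (cond in conds) {
    for (si in seq_along(series_names)) {
      nm <- series_names[si]
      base_sig <- sub("\\|.*$", "", nm)
      drop_sessions <- exclusions[[base_sig]] %||% integer(0)
      eps <- lapply(seq_along(epoch_list), function(i) {
        if (session_ids[i] %in% drop_sessions) return(NULL)
        e <- epoch_list[[i]][[cond]]
        if (is.null(e) || dim(e)[1] == 0) return(NULL)
        e[, , si, drop = FALSE]
      })
      eps <- eps[!vapply(eps, is.null, logical(1))]
      if (length(eps) == 0) next
      ep <- do.call(abind1, eps)
      av <- average_epochs(ep, t_epoch)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, series = nm, time_s = t_epoch,
        mean = av$mean[, 1], ci95 = av$ci95[, 1], n_epochs = av$n_epochs,
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

# Bind epoch arrays along the first (epoch) dimension.
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(p) dim(p)[1],
                                            integer(1))), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Run the full six-model comparison
#'
#' For each session: GLM-path preprocessing, physiology conditioning,
#' per-model design construction and OLS fit, ROI aggregation, denoised-signal
#' variance summaries, and block averaging. Across sessions: one-sample beta
#' significance tests, paired RMSE comparisons, per-ROI session variances, and
#' ICC(3,k) per model and chromophore. Deterministic given the seed. Sessions
#' failing at any stage are recorded and skipped.
#'
#' @param config a [pipeline_config()].
#' @return object of class `model_comparison`: list with `roi_betas`,
#'   `channel_betas`, `icc`, `session_variance`, `significance`,
#'   `rmse_comparison`, `denoise`, `lags`, `mean_lags`, `tcca`, `evoked`,
#'   `physio_evoked`, `failures`, `log`, `n_events`, `config`.
#' @export
run_model_comparison <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(config$input, "synthetic")) {
    dataset <- generate_dataset(config$sim)
    bundles <- dataset$sessions
  } else {
    dirs <- sort(list.dirs(config$input, recursive = FALSE))
    if (length(dirs) == 0) stop("no session directories under ", config$input)
    bundles <- lapply(seq_along(dirs), function(i) {
      b <- read_session_bundle(dirs[i])
      b$session <- i
      b
    })
    dataset <- NULL
  }

  results <- list()
  failures <- list()
  for (b in bundles) {
    res <- tryCatch(process_one_session(b, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        session = b$session, stage = "process_session",
        message = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- c(res, list(session = b$session))
    }
  }
  if (length(results) == 0) stop("every session failed")
  bind <- function(fld) {
    parts <- lapply(results, `[[`, fld)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0) NULL else do.call(rbind, parts)
  }
  roi_df <- bind("roi")
  channels_df <- bind("channels")
  denoise_df <- bind("denoise")
  lags_df <- bind("lags")
  tcca_df <- bind("tcca")
  log_df <- bind("log")
  session_ids <- vapply(results, `[[`, integer(1), "session")

  # Across-session statistics need at least two successful sessions.
  n_ok <- length(unique(roi_df$session))
  icc_rows <- list()
  var_rows <- list()
  sig_rows <- list()
  if (n_ok >= 2) for (model in config$models) for (k in CHROMA) {
    d <- roi_df[roi_df$model == model & roi_df$chroma == k &
                  roi_df$condition == "speech", ]
    ratings <- tapply(d$beta, list(d$session, d$roi), mean)
    r <- icc_3k(as.matrix(ratings))
    icc_rows[[length(icc_rows) + 1L]] <- data.frame(
      model = model, chroma = k, icc = r$icc, band = r$band %||% NA_character_,
      F = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
      n_sessions = r$n_targets, k_raters = r$k_raters)
    for (roi in unique(d$roi)) {
      v <- session_variance(d$beta[d$roi == roi])
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        model = model, chroma = k, roi = roi, variance = v)
    }
    for (cond in c("speech", "control")) {
      dd <- roi_df[roi_df$model == model & roi_df$chroma == k &
                     roi_df$condition == cond, ]
      m <- tapply(dd$beta, list(dd$session, dd$roi), mean)
      tt <- test_betas(as.matrix(m), alpha = config$alpha)
      tt <- cbind(model = model, chroma = k, condition = cond,
                  roi = tt$test, tt[, setdiff(names(tt), "test")])
      sig_rows[[length(sig_rows) + 1L]] <- tt
    }
  }
  icc_df <- if (length(icc_rows) > 0) do.call(rbind, icc_rows) else NULL
  var_df <- if (length(var_rows) > 0) do.call(rbind, var_rows) else NULL
  sig_df <- if (length(sig_rows) > 0) do.call(rbind, sig_rows) else NULL

  # Pairwise RMSE comparisons per ROI x chroma (>= 2 models, >= 2 sessions).
  cmp_rows <- list()
  if (length(config$models) >= 2 && n_ok >= 2) {
    sp <- roi_df[roi_df$condition == "speech", ]
    for (roi in unique(sp$roi)) for (k in CHROMA) {
      d <- sp[sp$roi == roi & sp$chroma == k,
              c("session", "model", "rmse")]
      names(d)[3] <- "rmse"
      cmp <- compare_model_rmse(d)
      cmp_rows[[length(cmp_rows) + 1L]] <- cbind(roi = roi, chroma = k, cmp)
    }
  }
  cmp_df <- if (length(cmp_rows) > 0) do.call(rbind, cmp_rows) else NULL

  mean_lags <- NULL
  if (!is.null(lags_df))
    mean_lags <- stats::aggregate(lag ~ signal, data = lags_df, FUN = mean)

  evoked <- NULL
  physio_evoked <- NULL
  if (isTRUE(config$block_average)) {
    ep_list <- lapply(results, `[[`, "epochs")
    evoked <- pool_epochs(ep_list, session_ids)
    evoked$roi <- sub("\\|.*$", "", evoked$series)
    evoked$chroma <- sub("^.*\\|", "", evoked$series)
    pep_list <- lapply(results, `[[`, "physio_epochs")
    physio_evoked <- pool_epochs(pep_list, session_ids,
                                 config$physio_exclusions)
    names(physio_evoked)[names(physio_evoked) == "series"] <- "signal"
  }

  structure(list(
    roi_betas = roi_df, channel_betas = channels_df, icc = icc_df,
    session_variance = var_df, significance = sig_df,
    rmse_comparison = cmp_df, denoise = denoise_df, lags = lags_df,
    mean_lags = mean_lags, tcca = tcca_df, evoked = evoked,
    physio_evoked = physio_evoked,
    failures = if (length(failures) > 0) do.call(rbind, failures) else NULL,
    log = log_df,
    n_events = vapply(results, `[[`, integer(1), "n_events"),
    sessions_run = session_ids,
    ground_truth = if (!is.null(dataset)) dataset$realized_betas else NULL,
    config = config), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("SPA-fNIRS model comparison:", length(x$sessions_run), "session(s),",
      length(unique(x$roi_betas$model)), "model(s)\n")
  if (!is.null(x$icc)) {
    cat("\nICC(3,k) per model and chromophore:\n")
    print(x$icc[, c("model", "chroma", "icc", "band")], row.names = FALSE)
  }
  if (!is.null(x$failures))
    cat("\n", nrow(x$failures), "session(s) failed\n")
  invisible(x)
}
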