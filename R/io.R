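# Plain-text interchange: session bundles (intensity CSV + channel table +
# physiology CSV + BIDS-style events TSV + ground-truth JSON sidecar) and
# tidy result tables with a manifest.

#' Write a session bundle to a directory
#'
#' Writes `intensity.csv` (wide: time_s plus one column per channel/wavelength),
#' `channels.csv`, `physio.csv` (schema: `time_s, heart_rate_bpm,
#' respiration_brpm, spo2_pct, ppg_au, gsr_us, temperature_c`), `events.tsv`
#' (`onset, duration, trial_type`) and, when ground truth is present,
#' `ground_truth.json`.
#'
#' @param bundle an `fnirs_session` (see [generate_session()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scan <- bundle$scan
  n <- dim(scan$intensity)[3]
  t_s <- (seq_len(n) - 1) / scan$sample_rate
  wide <- data.frame(time_s = t_s)
  for (c_i in seq_len(nrow(scan$channels)))
    for (w in 1:2)
      wide[[paste0(scan$channels$channel[c_i], "_", scan$wavelengths[w])]] <-
        scan$intensity[c_i, w, ]
  utils::write.csv(wide, file.path(dir, "intensity.csv"), row.names = FALSE)
  utils::write.csv(scan$channels, file.path(dir, "channels.csv"),
                   row.names = FALSE)

  t_p <- (seq_len(nrow(bundle$physio$signals)) - 1) /
    bundle$physio$sample_rate
  ph <- data.frame(t_p, bundle$physio$signals)
  names(ph) <- PHYSIO_CSV_COLUMNS
  utils::write.csv(ph, file.path(dir, "physio.csv"), row.names = FALSE)

  ev <- data.frame(onset = bundle$events$onset,
                   duration = bundle$events$duration,
                   trial_type = bundle$events$condition)
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    jsonlite::write_json(list(
      beta_roi_speech_hbo = as.list(tr$beta_roi_speech_hbo),
      beta_shift = tr$beta_shift,
      lags = as.list(tr$lags),
      coupling_gains = as.list(tr$coupling_gains),
      hbr_ratio = tr$hbr_ratio,
      sample_rate_fnirs = scan$sample_rate),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Counterpart of [write_session_bundle()].
#'
#' @param dir directory containing `intensity.csv`, `channels.csv`,
#'   `physio.csv` and `events.tsv`.
#' @return an `fnirs_session` (with `truth = NULL`; the JSON sidecar, when
#'   present, is attached as a plain list).
#' @export
read_session_bundle <- function(dir) {
  wide <- utils::read.csv(file.path(dir, "intensity.csv"))
  channels <- utils::read.csv(file.path(dir, "channels.csv"),
                              stringsAsFactors = FALSE)
  t_s <- wide$time_s
  fs <- 1 / stats::median(diff(t_s))
  wl <- unique(sub("^.*_", "", setdiff(names(wide), "time_s")))
  stopifnot(length(wl) == 2)
  n <- nrow(wide)
  intens <- array(NA_real_, dim = c(nrow(channels), 2L, n),
                  dimnames = list(channels$channel, wl, NULL))
  for (c_i in seq_len(nrow(channels)))
    for (w in 1:2)
      intens[c_i, w, ] <- wide[[paste0(channels$channel[c_i], "_", wl[w])]]
  scan <- raw_scan(intens, fs, channels, wavelengths = as.numeric(wl))

  ph <- utils::read.csv(file.path(dir, "physio.csv"))
  stopifnot(identical(names(ph), PHYSIO_CSV_COLUMNS))
  pr <- 1 / stats::median(diff(ph$time_s))
  signals <- as.matrix(ph[, -1])
  colnames(signals) <- PHYSIO_SIGNALS
  physio <- structure(list(signals = signals, sample_rate = pr),
                      class = "physio_record")

  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  events <- data.frame(onset = ev$onset, duration = ev$duration,
                       condition = ev$trial_type)
  truth <- NULL
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  structure(list(scan = scan, physio = physio, events = events,
                 truth = truth, session = NA_integer_),
            class = "fnirs_session")
}

#' Write model-comparison outputs as TSV/JSON with a manifest
#'
#' Writes each tidy result table (`roi_betas`, `channel_betas`, `icc`,
#' `session_variance`, `significance`, `rmse_comparison`, `denoise`, `lags`,
#' `mean_lags`, `evoked`, `physio_evoked`, `log`, `failures`) as TSV, and a
#' `manifest.json` listing every artifact with the md5 checksum of the
#' serialized configuration.
#'
#' @param result a [run_model_comparison()] result.
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
write_comparison_outputs <- function(result, dir) {
  stopifnot(inherits(result, "model_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("roi_betas", "channel_betas", "icc", "session_variance",
              "significance", "rmse_comparison", "denoise", "lags",
              "mean_lags", "tcca", "evoked", "physio_evoked", "log",
              "failures")
  written <- character(0)
  for (tb in tables) {
    d <- result[[tb]]
    if (is.null(d)) next
    f <- file.path(dir, paste0(tb, ".tsv"))
    utils::write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  cfg_file <- file.path(dir, "config.json")
  jsonlite::write_json(serialize_config(result$config), cfg_file,
                       auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, cfg_file)
  manifest <- list(schema_version = "1.0",
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   files = basename(written))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  invisible(c(written, mf))
}

serialize_config <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  lapply(unclass(cfg), strip)
}
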