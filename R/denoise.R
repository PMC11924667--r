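# Nuisance regression denoising: Y_filtered = Y_raw - sum(beta_g X_g) over
# the selected nuisance groups, with betas from the simultaneous (richest)
# GLM estimation. Stimulus and intercept contributions are never subtracted.

#' Subtract weighted nuisance contributions from the raw signal
#'
#' Computes `Y_filtered = Y_raw - sum over selected groups of beta_i * X_i`
#' using betas estimated simultaneously in the supplied fit. Selecting
#' `physio` yields the physiology-removed signal; `ss` the short-channel
#' removed signal; `c("physio", "ss")` both; `c("lag_physio", "ss")` the
#' lagged-physiology variant; `c("tcca", "ss")` the latent-component variant.
#'
#' @param Y_raw numeric matrix `n x channels`: the same response matrix the
#'   fit was estimated on.
#' @param fit a [fit_ols()] result estimated from `design` on `Y_raw`.
#' @param design the [build_design_matrix()] object used for `fit`.
#' @param groups character vector of nuisance group names to subtract; subset
#'   of `{"physio", "ss", "lag_physio", "tcca"}` present in the design.
#' @return object of class `denoised_series`: list with `values` (same shape
#'   as `Y_raw`) and `removed_sets`.
#' @export
regress_out <- function(Y_raw, fit, design, groups) {
  if (is.null(dim(Y_raw))) Y_raw <- matrix(Y_raw, ncol = 1)
  stopifnot(inherits(fit, "glm_fit"), length(groups) > 0)
  allowed <- c("physio", "ss", "lag_physio", "tcca")
  if (!all(groups %in% allowed))
    stop("groups must be nuisance sets: ", paste(allowed, collapse = ", "))
  missing_g <- setdiff(groups, names(design$groups))
  if (length(missing_g) > 0)
    stop("group(s) absent from the design: ",
         paste(missing_g, collapse = ", "))
  common_cols <- unlist(design$groups[setdiff(groups, "lag_physio")],
                        use.names = FALSE)
  contrib <- matrix(0, nrow(Y_raw), ncol(Y_raw))
  if (length(common_cols) > 0)
    contrib <- contrib + design$X[, common_cols, drop = FALSE] %*%
      fit$beta[common_cols, , drop = FALSE]
  if ("lag_physio" %in% groups) {
    cols <- design$groups$lag_physio
    for (j in seq_len(ncol(Y_raw)))
      contrib[, j] <- contrib[, j] +
        design$per_channel[[j]][, cols, drop = FALSE] %*%
          fit$beta[cols, j]
  }
  structure(list(values = Y_raw - contrib, removed_sets = sort(groups)),
            class = "denoised_series")
}
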