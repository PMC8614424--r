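#' Spectral outlier screening by Mahalanobis distance in PCA score space
#'
#' PCA on the centered spectra; the smallest number of components
#' explaining at least `var_explained` of the variance (capped at
#' `max_components`) is retained. The GH statistic of sample *i* is its
#' squared Mahalanobis distance in score space divided by the number of
#' retained components, so the fitting-set mean GH is close to 1. Samples
#' with `GH > threshold` are flagged as spectral outliers.
#'
#' @param s a `spectra_set` (pretreated or raw), n >= 10.
#' @param threshold GH cut-off, default 3.
#' @param var_explained variance fraction the retained components must
#'   reach, default 0.99.
#' @param max_components cap on retained components, default 20.
#' @return an object of class `gh_report`: data frame-ish list with
#'   `sample_id`, `gh`, `keep` plus `n_components` and `threshold`.
#' @export
pca_gh_screen <- function(s, threshold = 3, var_explained = 0.99, max_components = 20) {
  stopifnot(inherits(s, "spectra_set"))
  X <- s$absorbance
  n <- nrow(X)
  if (n < 10) stopf("GH screening is unstable below 10 samples (n = %d)", n)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = min(n, ncol(X)), nv = 0)
  d2 <- sv$d^2
  pos <- d2 > d2[1] * 1e-24
  cum <- cumsum(d2[pos]) / sum(d2[pos])
  K <- min(which(cum >= var_explained)[1], max_components, sum(pos), n - 1)
  # scores = U d; score SD_k = d_k / sqrt(n-1); standardized scores = U * sqrt(n-1)
  U <- sv$u[, seq_len(K), drop = FALSE]
  gh <- rowSums(U^2) * (n - 1) / K
  structure(
    list(sample_id = s$sample_ids, gh = gh, keep = gh <= threshold,
         n_components = K, threshold = threshold),
    class = "gh_report"
  )
}

#' @export
print.gh_report <- function(x, ...) {
  cat(sprintf("<gh_report> %d samples, %d components, threshold %.2f: %d flagged\n",
              length(x$gh), x$n_components, x$threshold, sum(!x$keep)))
  invisible(x)
}

#' Write a GH report as CSV
#' @param report a `gh_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gh_report <- function(report, path) {
  df <- data.frame(sample_id = report$sample_id,
                   gh = sprintf("%.6f", report$gh),
                   kept = report$keep)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Iterative compositional outlier removal
#'
#' Cross-validates, flags samples whose cross-validated prediction differs
#' from the reference value by more than `multiplier` times the SECV, drops
#' them, and refits; stops when a pass flags nothing or `max_passes` is
#' reached. The kept set only shrinks. With `multiplier = Inf` nothing is
#' ever removed and the final model is a plain fit.
#'
#' @inheritParams cross_validate
#' @param multiplier residual cut-off in SECV units (default 3).
#' @param max_passes maximum elimination passes (default 2).
#' @param sample_ids optional ids used in the removal log.
#' @return list with `keep` (logical mask over the input rows), `model`
#'   (final `mpls_model` fitted on the kept samples, `chosen_factors` set
#'   from the last cross-validation), `cv` (last `cv_result`), `passes`,
#'   and `log` (character lines, one per removal).
#' @export
compositional_screen <- function(X, y, groups = 4, multiplier = 3, max_passes = 2,
                                 max_factors = 16, seed = 1,
                                 standardize_residuals = TRUE, tolerance = 1.02,
                                 sample_ids = NULL) {
  if (multiplier <= 0) stopf("multiplier must be > 0")
  if (max_passes < 1) stopf("max_passes must be >= 1")
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  ids <- sample_ids %||% as.character(seq_len(n))
  keep <- rep(TRUE, n)
  log_lines <- character()
  cv <- NULL
  dropped_last <- FALSE
  for (pass in seq_len(max_passes)) {
    cv <- cross_validate(X[keep, , drop = FALSE], y[keep], groups = groups,
                         max_factors = max_factors, seed = seed,
                         standardize_residuals = standardize_residuals,
                         tolerance = tolerance)
    dropped_last <- FALSE
    secv <- cv$secv[cv$chosen_factors]
    if (!is.finite(multiplier)) break
    resid <- abs(cv$cv_predictions - y[keep])
    flag <- resid > multiplier * secv
    if (!any(flag)) break
    kept_idx <- which(keep)
    for (j in which(flag)) {
      log_lines <- c(log_lines, sprintf(
        "pass %d: removed %s (|residual|/SECV = %.2f)",
        pass, ids[kept_idx[j]], resid[j] / secv))
    }
    keep[kept_idx[flag]] <- FALSE
    dropped_last <- TRUE
    if (sum(keep) < 2 * groups) stopf("pathological data: too few samples survive screening")
  }
  if (dropped_last) {  # passes exhausted right after a removal: refresh CV stats
    cv <- cross_validate(X[keep, , drop = FALSE], y[keep], groups = groups,
                         max_factors = max_factors, seed = seed,
                         standardize_residuals = standardize_residuals,
                         tolerance = tolerance)
  }
  if (!any(keep)) stopf("pathological data: all samples flagged as compositional outliers")
  model <- suppressWarnings(fit_mpls(X[keep, , drop = FALSE], y[keep],
                                     max_factors = max_factors,
                                     standardize_residuals = standardize_residuals))
  model$chosen_factors <- min(cv$chosen_factors, model$n_factors)
  model$coefficients <- mpls_coefficients(model, model$chosen_factors)
  list(keep = keep, model = model, cv = cv,
       passes = if (is.null(cv)) 0L else pass, log = log_lines)
}
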