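#' Calibration statistics
#'
#' The model-quality statistics of a calibration:
#' `SEC = sqrt(sum((yhat - y)^2) / (n - 1 - k))` (factors consume degrees
#' of freedom), `SECV = sqrt(sum((yhat_cv - y)^2) / n)`,
#' `RSQ_C = 1 - SS_res / SS_tot`, and `1-VR = 1 - SS_res_cv / SS_tot`
#' (cross-validated R-squared).
#'
#' @param y reference values (%% DM).
#' @param y_hat in-sample fitted values.
#' @param y_cv cross-validated predictions.
#' @param k number of latent factors used.
#' @return an object of class `calibration_stats`: list with `n`, `k`,
#'   `sec`, `secv`, `rsq_c`, `one_minus_vr`.
#' @export
calibration_stats <- function(y, y_hat, y_cv, k) {
  n <- length(y)
  stopifnot(length(y_hat) == n, length(y_cv) == n)
  if (n < k + 2) stopf("need n >= k + 2 (n = %d, k = %d)", n, k)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("zero variance in reference values")
  sec <- sqrt(sum((y_hat - y)^2) / (n - 1 - k))
  secv <- sqrt(sum((y_cv - y)^2) / n)
  structure(
    list(n = n, k = k, sec = sec, secv = secv,
         rsq_c = 1 - sum((y_hat - y)^2) / ss_tot,
         one_minus_vr = 1 - sum((y_cv - y)^2) / ss_tot),
    class = "calibration_stats"
  )
}

#' External validation statistics
#'
#' With prediction errors `e = y_hat - y` (bias convention: predicted minus
#' reference): `bias = mean(e)`, `SEP = sqrt(sum(e^2)/n)`,
#' `SEP(C) = sqrt(sum((e - bias)^2)/(n - 1))` (bias-corrected), `slope`
#' from the least-squares regression of the laboratory value on the
#' prediction, `RSQ_V` the squared Pearson correlation, and
#' `RPD = SD_val / SEP` where `SD_val` is the validation-set reference SD.
#'
#' @param y validation reference values (%% DM).
#' @param y_hat predictions.
#' @param sd_val validation-set reference standard deviation; defaults to
#'   `sd(y)` but can be given explicitly (e.g. a published value).
#' @return an object of class `validation_stats`: list with `n`, `bias`,
#'   `sep`, `sep_c`, `slope`, `rsq_v`, `rpd`, `sd_val`.
#' @export
validation_stats <- function(y, y_hat, sd_val = stats::sd(y)) {
  n <- length(y)
  stopifnot(length(y_hat) == n)
  if (n < 3) stopf("need at least 3 validation samples")
  if (!is.finite(sd_val) || sd_val <= 0) stopf("SD of the validation set must be > 0")
  if (stats::sd(y_hat) == 0) stopf("constant predictions: slope and correlation undefined")
  e <- y_hat - y
  bias <- mean(e)
  sep <- sqrt(sum(e^2) / n)
  if (sep == 0) stopf("zero SEP: RPD undefined")
  sep_c <- sqrt(sum((e - bias)^2) / (n - 1))
  slope <- unname(stats::coef(stats::lm(y ~ y_hat))[2])
  structure(
    list(n = n, bias = bias, sep = sep, sep_c = sep_c, slope = slope,
         rsq_v = stats::cor(y, y_hat)^2, rpd = sd_val / sep, sd_val = sd_val),
    class = "validation_stats"
  )
}

#' Coefficient of variation
#'
#' `CV = 100 * SD / mean`, in percent, reported to 2 decimals.
#'
#' @param mean constituent mean, must be > 0.
#' @param sd constituent standard deviation.
#' @return CV in percent, rounded to 2 decimals.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean <= 0)) stopf("CV requires a positive mean")
  round(100 * sd / mean, 2)
}

#' Hemicellulose from fiber fractions
#'
#' Hemicellulose (%) = NDF% - ADF%.
#'
#' @param ndf neutral detergent fiber, %% DM.
#' @param adf acid detergent fiber, %% DM; must not exceed NDF.
#' @return hemicellulose, %% DM.
#' @export
hemicellulose_from_fiber <- function(ndf, adf) {
  if (any(adf < 0) || any(ndf < adf)) stopf("requires NDF >= ADF >= 0")
  ndf - adf
}

.model_bands <- data.frame(
  label = c("excellent", "successful", "moderately_successful",
            "moderately_useful"),
  rsq = c(0.95, 0.90, 0.80, 0.70),
  rpd = c(4.0, 3.0, 2.25, 1.75)
)

#' Classify model quality from RSQ and RPD
#'
#' Quality bands for environmental/forage calibrations: excellent
#' (RSQ >= 0.95 and RPD >= 4.0), successful (0.90/3.0), moderately
#' successful (0.80/2.25), moderately useful (0.70/1.75); anything weaker
#' is useful for screening only. Bands are evaluated best-first; a model
#' must meet *both* lower bounds (inclusive) of a band to earn its label.
#' Whether the calibration or the validation R-squared is classified is the
#' caller's choice; pass it explicitly.
#'
#' @param rsq coefficient of determination in `[0, 1]`.
#' @param rpd ratio of prediction to deviation, >= 0.
#' @return the class label, one of `"excellent"`, `"successful"`,
#'   `"moderately_successful"`, `"moderately_useful"`, `"screening_only"`.
#' @export
classify_model <- function(rsq, rpd) {
  stopifnot(rsq >= 0, rsq <= 1, rpd >= 0)
  for (i in seq_len(nrow(.model_bands))) {
    if (rsq >= .model_bands$rsq[i] && rpd >= .model_bands$rpd[i]) {
      return(.model_bands$label[i])
    }
  }
  "screening_only"
}
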