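#' Published reference statistics for corn stover and wheat straw
#'
#' Summary statistics from a published corn-stover / wheat-straw NIRS
#' calibration study, shipped as plain CSV: wet-chemistry descriptive
#' statistics (per species and for the pooled set, calibration and
#' validation subsets) and the external-validation statistics of the
#' optimal models. They serve as worked-example inputs: e.g. the printed
#' validation SD and SEP reproduce the printed RPD, and the printed
#' mean/SD reproduce the printed CV.
#'
#' @param which `"descriptive"` (min/max/mean/SD/CV per constituent and
#'   set) or `"validation"` (bias, SEP, SEP(C), slope, RSQ_V, RPD plus the
#'   validation-set SD).
#' @return a data frame.
#' @export
published_stats <- function(which = c("descriptive", "validation")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("published_%s_stats.csv", which),
                   package = "nirscal", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
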