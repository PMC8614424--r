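#' Rank-stratified calibration/validation split
#'
#' Samples with a reference value for the constituent are sorted ascending
#' (ties broken by sample id); within each consecutive block of `fold`
#' samples the one at position `offset` (0-based) goes to validation, the
#' rest to calibration. With the default `offset = fold %/% 2` the
#' validation set avoids the extreme minimum and maximum values, so the
#' validation range stays inside the calibration range. Deterministic.
#'
#' @param ref a [reference_table()].
#' @param constituent column name to stratify on.
#' @param fold block size; one of every `fold` samples validates
#'   (default 5, i.e. about four-fifths calibrate).
#' @param offset position within each block sent to validation, in
#'   `[0, fold)`.
#' @return an object of class `split_plan`: list with `constituent`,
#'   `calibration` and `validation` id vectors, `fold`, `offset`.
#' @export
rank_stratified_split <- function(ref, constituent, fold = 5, offset = fold %/% 2) {
  if (!constituent %in% names(ref)) stopf("constituent %s not in reference table", constituent)
  if (fold < 2) stopf("fold must be >= 2")
  if (offset < 0 || offset >= fold) stopf("offset must be in [0, fold)")
  v <- ref[[constituent]]
  miss <- is.na(v)
  if (mean(miss) > 0.2) {
    stopf("constituent %s missing for %.0f%% of samples", constituent, 100 * mean(miss))
  }
  ids <- ref$sample_id[!miss]
  vals <- v[!miss]
  ord <- order(vals, ids)
  ids <- ids[ord]
  pos0 <- (seq_along(ids) - 1) %% fold
  val <- ids[pos0 == offset]
  cal <- ids[pos0 != offset]
  structure(
    list(constituent = constituent, calibration = cal, validation = val,
         fold = fold, offset = offset),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d calibration / %d validation (fold %d, offset %d)\n",
              x$constituent, length(x$calibration), length(x$validation),
              x$fold, x$offset))
  invisible(x)
}

#' Build a pretreatment grid
#'
#' Cartesian product of math treatments and scatter corrections,
#' deduplicated. The default grid — five math treatments
#' `(0,0,1,1), (1,4,4,1), (2,4,4,1), (1,8,8,1), (2,8,8,1)` crossed with six
#' scatter corrections (none, SNV, detrend, standard and weighted MSC,
#' mean-scale + linear detrend) — yields the 30 candidate pretreatments
#' searched per constituent.
#'
#' @param maths list of [math_treatment()]s (or 4-vectors).
#' @param scatters character vector of scatter labels (see
#'   [pretreatment()]).
#' @return list of `pretreatment` objects.
#' @export
build_grid <- function(maths = default_math_grid(), scatters = default_scatter_grid()) {
  if (!length(maths) || !length(scatters)) stopf("grid inputs must be non-empty")
  out <- list()
  seen <- character()
  for (m in maths) {
    for (sc in scatters) {
      p <- pretreatment(m, sc)
      key <- format_pretreatment(p)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- p
      }
    }
  }
  out
}

#' @rdname build_grid
#' @export
default_math_grid <- function() {
  list(math_treatment(0, 0, 1, 1), math_treatment(1, 4, 4, 1),
       math_treatment(2, 4, 4, 1), math_treatment(1, 8, 8, 1),
       math_treatment(2, 8, 8, 1))
}

#' @rdname build_grid
#' @export
default_scatter_grid <- function() {
  c("none", "snv_only", "detrend_only", "msc_standard", "msc_weighted",
    "scale_linear")
}

#' Pretreatment grid search
#'
#' For each candidate pretreatment: apply it to the calibration spectra,
#' run the compositional outlier screen (which cross-validates and fits),
#' and collect calibration statistics. Candidates are ranked primarily by
#' 1-VR descending with SECV ascending as tie-break: both are
#' cross-validated and therefore honest, whereas SEC and RSQ_C are
#' in-sample. A pretreatment that fails (e.g. window larger than the
#' spectrum) is recorded as failed, not fatal.
#'
#' @param spectra calibration `spectra_set`.
#' @param ref a [reference_table()] covering the calibration samples.
#' @param constituent response column name.
#' @param grid list of [pretreatment()]s, e.g. from [build_grid()].
#' @param groups,max_factors,seed,standardize_residuals,tolerance passed to
#'   [cross_validate()] via [compositional_screen()].
#' @param secv_multiplier,max_passes compositional screen settings.
#' @return an object of class `grid_search_result`: list with `candidates`
#'   (each holding `pretreatment`, `state`, `model`, `stats`, `keep`,
#'   `status`), best first, and `report` (one data-frame row per
#'   candidate).
#' @export
grid_search <- function(spectra, ref, constituent, grid = build_grid(),
                        groups = 4, max_factors = 16, seed = 1,
                        standardize_residuals = TRUE, tolerance = 1.02,
                        secv_multiplier = 3, max_passes = 2) {
  if (!length(grid)) stopf("empty pretreatment grid")
  idx <- match(spectra$sample_ids, ref$sample_id)
  if (anyNA(idx)) stopf("spectra contain samples absent from the reference table")
  y_all <- ref[[constituent]][idx]
  ok <- !is.na(y_all)
  s_use <- spectra[which(ok)]
  y <- y_all[ok]
  candidates <- lapply(grid, function(p) {
    res <- tryCatch({
      pre <- apply_pretreatment(s_use, p)
      scr <- compositional_screen(
        pre$spectra$absorbance, y, groups = groups,
        multiplier = secv_multiplier, max_passes = max_passes,
        max_factors = max_factors, seed = seed,
        standardize_residuals = standardize_residuals, tolerance = tolerance,
        sample_ids = s_use$sample_ids)
      yk <- y[scr$keep]
      fitted <- predict(scr$model, pre$spectra$absorbance[scr$keep, , drop = FALSE],
                        k = scr$model$chosen_factors)
      st <- calibration_stats(yk, fitted, scr$cv$cv_predictions,
                              scr$model$chosen_factors)
      scr$model$pretreatment <- format_pretreatment(p)
      list(pretreatment = p, state = pre$state, model = scr$model, stats = st,
           keep = scr$keep, screen_log = scr$log, status = "ok")
    }, error = function(e) {
      list(pretreatment = p, state = NULL, model = NULL, stats = NULL,
           keep = NULL, screen_log = character(),
           status = paste("failed:", conditionMessage(e)))
    })
    res
  })
  ok_mask <- vapply(candidates, function(cand) identical(cand$status, "ok"), logical(1))
  key1 <- vapply(candidates, function(cand) if (identical(cand$status, "ok")) cand$stats$one_minus_vr else -Inf, numeric(1))
  key2 <- vapply(candidates, function(cand) if (identical(cand$status, "ok")) cand$stats$secv else Inf, numeric(1))
  ord <- order(-key1, key2,
               vapply(candidates, function(cand) format_pretreatment(cand$pretreatment), character(1)))
  candidates <- candidates[ord]
  report <- do.call(rbind, lapply(candidates, function(cand) {
    if (identical(cand$status, "ok")) {
      data.frame(pretreatment = format_pretreatment(cand$pretreatment),
                 n = cand$stats$n, factors = cand$stats$k,
                 sec = cand$stats$sec, secv = cand$stats$secv,
                 rsq_c = cand$stats$rsq_c, one_minus_vr = cand$stats$one_minus_vr,
                 status = "ok", stringsAsFactors = FALSE)
    } else {
      data.frame(pretreatment = format_pretreatment(cand$pretreatment),
                 n = NA_integer_, factors = NA_integer_, sec = NA_real_,
                 secv = NA_real_, rsq_c = NA_real_, one_minus_vr = NA_real_,
                 status = cand$status, stringsAsFactors = FALSE)
    }
  }))
  if (!any(ok_mask)) stopf("every pretreatment in the grid failed")
  structure(list(candidates = candidates, report = report, constituent = constituent),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  best <- x$candidates[[1]]
  cat(sprintf("<grid_search_result> %s: %d candidates; best %s (1-VR %.4f, SECV %.4f)\n",
              x$constituent, length(x$candidates),
              format_pretreatment(best$pretreatment),
              best$stats$one_minus_vr, best$stats$secv))
  invisible(x)
}
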