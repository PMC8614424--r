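#' Build a run configuration
#'
#' One config drives the whole workflow: data source (simulation profiles
#' or CSV paths), the constituents to calibrate, and every stage parameter.
#' A JSON copy of the config is written next to the outputs so a run can be
#' reproduced from its artifacts.
#'
#' @param output_dir directory for reports, or `NULL` to skip writing.
#' @param seed master seed; every stage draws from named substreams of it.
#' @param constituents constituent columns to calibrate.
#' @param n_per_species simulated samples per species (ignored when reading
#'   from files).
#' @param profiles list of [simulation_profile()]s, one per species; their
#'   seeds are re-derived from `seed` so the run is reproducible from the
#'   config alone.
#' @param spectra_path,reference_path optional CSV paths; when given they
#'   replace simulation (the spectra file must carry a species column for
#'   per-species work).
#' @param grid_step simulator grid step, nm.
#' @param grid list of [pretreatment()]s to search.
#' @param fold,offset split parameters ([rank_stratified_split()]).
#' @param groups cross-validation groups.
#' @param max_factors maximum MPLS factors.
#' @param gh_threshold spectral outlier cut-off ([pca_gh_screen()]).
#' @param secv_multiplier,max_passes compositional screen settings.
#' @param tolerance SECV parsimony tolerance for factor choice.
#' @param classify_on `"rsq_c"` or `"rsq_v"`: which R-squared feeds the
#'   quality classification (reported alongside the label).
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir = NULL, seed = 1,
                       constituents = constituent_names(),
                       n_per_species = 120,
                       profiles = list(corn_stover_profile(), wheat_straw_profile()),
                       spectra_path = NULL, reference_path = NULL,
                       grid_step = 2, grid = build_grid(),
                       fold = 5, offset = fold %/% 2, groups = 4,
                       max_factors = 16, gh_threshold = 3,
                       secv_multiplier = 3, max_passes = 2, tolerance = 1.02,
                       classify_on = c("rsq_c", "rsq_v")) {
  classify_on <- match.arg(classify_on)
  structure(
    list(output_dir = output_dir, seed = as.integer(seed),
         constituents = constituents, n_per_species = n_per_species,
         profiles = profiles, spectra_path = spectra_path,
         reference_path = reference_path, grid_step = grid_step, grid = grid,
         fold = fold, offset = offset, groups = groups,
         max_factors = max_factors, gh_threshold = gh_threshold,
         secv_multiplier = secv_multiplier, max_passes = max_passes,
         tolerance = tolerance, classify_on = classify_on),
    class = "run_config"
  )
}

config_to_json <- function(cfg, path) {
  obj <- cfg
  obj$grid <- vapply(cfg$grid, format_pretreatment, character(1))
  obj$profiles <- lapply(cfg$profiles, unclass)
  jsonlite::write_json(unclass(obj), path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Load or simulate the data a config describes
#'
#' When paths are configured, reads them; otherwise draws
#' `n_per_species` samples per configured profile (profile seeds re-derived
#' from the config seed) and pools them with species labels.
#'
#' @param cfg a [run_config()].
#' @return list with `spectra` (`spectra_set`) and `reference`
#'   (`reference_table`), species-labelled.
#' @export
acquire_data <- function(cfg) {
  if (!is.null(cfg$spectra_path)) {
    return(list(spectra = read_spectra(cfg$spectra_path),
                reference = read_reference(cfg$reference_path)))
  }
  grid <- default_wavelength_grid(cfg$grid_step)
  lib <- default_band_library(grid)
  sets <- lapply(seq_along(cfg$profiles), function(i) {
    prof <- cfg$profiles[[i]]
    prof$seed <- substream_seed(cfg$seed, "simulate", i)
    simulate_species(prof, cfg$n_per_species, grid, lib)
  })
  spectra <- sets[[1]]$spectra
  reference <- sets[[1]]$reference
  for (s in sets[-1]) {
    spectra <- spectra_set(
      spectra$wavelengths,
      rbind(spectra$absorbance, s$spectra$absorbance),
      c(spectra$sample_ids, s$spectra$sample_ids),
      c(spectra$species, s$spectra$species))
    reference <- reference_table(
      c(reference$sample_id, s$reference$sample_id),
      rbind(as.data.frame(reference)[ref_constituents(reference)],
            as.data.frame(s$reference)[ref_constituents(s$reference)]),
      species = c(reference$species, s$reference$species))
  }
  list(spectra = spectra, reference = reference)
}

fmt4 <- function(x) sprintf("%.4f", x)

# one constituent: GH screen -> split -> grid search -> external validation
calibrate_constituent <- function(spectra, reference, constituent, cfg, label) {
  gh <- pca_gh_screen(spectra, threshold = cfg$gh_threshold)
  kept <- spectra[which(gh$keep)]
  ref_kept <- reference[reference$sample_id %in% kept$sample_ids, ]
  split <- rank_stratified_split(ref_kept, constituent, fold = cfg$fold,
                                 offset = cfg$offset)
  cal_s <- kept[split$calibration]
  gs <- grid_search(cal_s, ref_kept, constituent, grid = cfg$grid,
                    groups = cfg$groups, max_factors = cfg$max_factors,
                    seed = substream_seed(cfg$seed, "screen"),
                    tolerance = cfg$tolerance,
                    secv_multiplier = cfg$secv_multiplier,
                    max_passes = cfg$max_passes)
  best <- gs$candidates[[1]]
  val_s <- kept[split$validation]
  val_pre <- apply_pretreatment(val_s, best$pretreatment, state = best$state)
  y_val <- ref_kept[[constituent]][match(split$validation, ref_kept$sample_id)]
  keep_val <- !is.na(y_val)
  y_val <- y_val[keep_val]
  y_pred <- predict(best$model, val_pre$spectra$absorbance[keep_val, , drop = FALSE])
  vstats <- validation_stats(y_val, y_pred)
  rsq_used <- if (cfg$classify_on == "rsq_c") best$stats$rsq_c else vstats$rsq_v
  y_cal <- ref_kept[[constituent]][match(split$calibration, ref_kept$sample_id)]
  list(constituent = constituent, set = label, status = "ok",
       cal_sd = stats::sd(y_cal[!is.na(y_cal)]),
       gh = gh, split = split, grid = gs, model = best$model,
       pretreatment = format_pretreatment(best$pretreatment),
       cal_stats = best$stats, val_stats = vstats,
       class = classify_model(max(0, min(1, rsq_used)), vstats$rpd),
       rsq_used = cfg$classify_on,
       predictions = data.frame(sample_id = split$validation[keep_val],
                                reference = y_val, predicted = y_pred))
}

stats_row <- function(res) {
  data.frame(
    constituent = res$constituent, set = res$set,
    n_cal = res$cal_stats$n, pretreatment = res$pretreatment,
    factors = res$cal_stats$k,
    rsq_c = fmt4(res$cal_stats$rsq_c), sec = fmt4(res$cal_stats$sec),
    secv = fmt4(res$cal_stats$secv), one_minus_vr = fmt4(res$cal_stats$one_minus_vr),
    n_val = res$val_stats$n, bias = fmt4(res$val_stats$bias),
    sep = fmt4(res$val_stats$sep), sep_c = fmt4(res$val_stats$sep_c),
    slope = fmt4(res$val_stats$slope), rsq_v = fmt4(res$val_stats$rsq_v),
    rpd = sprintf("%.3f", res$val_stats$rpd),
    class = res$class, rsq_used = res$rsq_used,
    stringsAsFactors = FALSE
  )
}

write_bundle <- function(bundle, cfg, label) {
  if (is.null(cfg$output_dir)) return(invisible(NULL))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(cfg$output_dir, label)
  dir.create(base, showWarnings = FALSE)
  utils::write.csv(bundle$stats, file.path(base, "stats.csv"),
                   row.names = FALSE, quote = FALSE)
  con <- file(file.path(base, "log.jsonl"), "w"); on.exit(close(con))
  for (res in bundle$results) {
    if (!identical(res$status, "ok")) {
      writeLines(jsonlite::toJSON(list(constituent = res$constituent,
                                       status = res$status), auto_unbox = TRUE), con)
      next
    }
    cdir <- file.path(base, res$constituent)
    dir.create(cdir, showWarnings = FALSE)
    write_gh_report(res$gh, file.path(cdir, "gh_report.csv"))
    utils::write.csv(
      data.frame(sample_id = c(res$split$calibration, res$split$validation),
                 role = c(rep("calibration", length(res$split$calibration)),
                          rep("validation", length(res$split$validation)))),
      file.path(cdir, "split.csv"), row.names = FALSE, quote = FALSE)
    rep_df <- res$grid$report
    rep_df[c("sec", "secv", "rsq_c", "one_minus_vr")] <-
      lapply(rep_df[c("sec", "secv", "rsq_c", "one_minus_vr")], fmt4)
    utils::write.csv(rep_df, file.path(cdir, "grid_report.csv"),
                     row.names = FALSE, quote = FALSE)
    model_to_json(res$model, file.path(cdir, "model.json"))
    pred_df <- res$predictions
    pred_df[c("reference", "predicted")] <- lapply(pred_df[c("reference", "predicted")], fmt4)
    utils::write.csv(pred_df, file.path(cdir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(jsonlite::toJSON(list(
      constituent = res$constituent, status = "ok",
      n_cal = res$cal_stats$n, n_val = res$val_stats$n,
      pretreatment = res$pretreatment, factors = res$cal_stats$k,
      secv = round(res$cal_stats$secv, 6), rpd = round(res$val_stats$rpd, 3),
      class = res$class), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(NULL)
}

run_workflow_on <- function(spectra, reference, cfg, label) {
  results <- lapply(cfg$constituents, function(con) {
    tryCatch(calibrate_constituent(spectra, reference, con, cfg, label),
             error = function(e) list(constituent = con, set = label,
                                      status = paste("failed:", conditionMessage(e))))
  })
  ok <- vapply(results, function(r) identical(r$status, "ok"), logical(1))
  stats <- if (any(ok)) do.call(rbind, lapply(results[ok], stats_row))
  bundle <- list(set = label, results = results, stats = stats,
                 failed = vapply(results[!ok], function(r) r$constituent, character(1)))
  write_bundle(bundle, cfg, label)
  bundle
}

#' Run the single-species calibration workflow
#'
#' Per constituent: GH spectral screen, rank-stratified split, pretreatment
#' grid search on the calibration set (with compositional outlier removal
#' inside), external validation of the winner, statistics and quality
#' class. A failing constituent is logged and skipped, never fatal to the
#' others.
#'
#' @param cfg a [run_config()].
#' @param species species label to run (must match the data's labels).
#' @param data optional pre-acquired `list(spectra, reference)`; defaults
#'   to [acquire_data()] on the config.
#' @return a report bundle: list with `set`, `results` (per constituent),
#'   `stats` (data frame mirroring the reported statistics), `failed`.
#' @export
run_species_workflow <- function(cfg, species, data = acquire_data(cfg)) {
  if (is.null(data$spectra$species)) stopf("data carry no species labels")
  sel <- data$spectra$species == species
  if (!any(sel)) stopf("no samples for species %s", species)
  spectra <- data$spectra[which(sel)]
  reference <- data$reference[data$reference$sample_id %in% spectra$sample_ids, ]
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    config_to_json(cfg, file.path(cfg$output_dir, "config.json"))
  }
  run_workflow_on(spectra, reference, cfg, species)
}

#' Run the combined (pooled-species) workflow
#'
#' Pools all species, reruns the full workflow on the pooled set, and emits
#' a comparison table: per constituent, each single-species validation RPD
#' against the combined RPD, with the calibration-set SDs that drive the
#' difference (a wider pooled calibration range raises the SD, and RPD
#' scales with it).
#'
#' @param cfg a [run_config()].
#' @param data optional pre-acquired data.
#' @param species_bundles optional list of per-species bundles (from
#'   [run_species_workflow()]); computed here when absent.
#' @return list with `combined` (the pooled bundle), `species` (per-species
#'   bundles) and `comparison` (data frame).
#' @export
run_combined_workflow <- function(cfg, data = acquire_data(cfg), species_bundles = NULL) {
  if (is.null(data$spectra$species)) stopf("data carry no species labels")
  species <- unique(data$spectra$species)
  if (length(species) < 2) stopf("combined workflow needs >= 2 species")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    config_to_json(cfg, file.path(cfg$output_dir, "config.json"))
  }
  if (is.null(species_bundles)) {
    species_bundles <- lapply(species, function(sp) run_species_workflow(cfg, sp, data))
    names(species_bundles) <- species
  }
  combined <- run_workflow_on(data$spectra, data$reference, cfg, "combined")
  comparison <- do.call(rbind, lapply(cfg$constituents, function(con) {
    row <- data.frame(constituent = con, stringsAsFactors = FALSE)
    for (sp in species) {
      r <- Filter(function(x) x$constituent == con && identical(x$status, "ok"),
                  species_bundles[[sp]]$results)
      row[[paste0("rpd_", sp)]] <- if (length(r)) r[[1]]$val_stats$rpd else NA_real_
      row[[paste0("cal_sd_", sp)]] <- if (length(r)) r[[1]]$cal_sd else NA_real_
    }
    rc <- Filter(function(x) x$constituent == con && identical(x$status, "ok"),
                 combined$results)
    row$rpd_combined <- if (length(rc)) rc[[1]]$val_stats$rpd else NA_real_
    row$cal_sd_combined <- if (length(rc)) rc[[1]]$cal_sd else NA_real_
    row
  }))
  if (!is.null(cfg$output_dir)) {
    out <- comparison
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) sprintf("%.3f", x))
    utils::write.csv(out, file.path(cfg$output_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(combined = combined, species = species_bundles, comparison = comparison)
}
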