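#' Construct a spectra set
#'
#' A `spectra_set` holds absorbance spectra, `log(1/R)`, for a collection of
#' samples on a shared, strictly increasing, uniformly spaced wavelength grid
#' (nm). It is the object every pipeline stage transforms.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing with a constant step (checked to 1e-9 nm).
#' @param absorbance numeric matrix of absorbance values, one row per sample,
#'   `length(wavelengths)` columns, all finite.
#' @param sample_ids unique character ids, one per row.
#' @param species optional character vector of species labels per sample
#'   (e.g. `"corn_stover"`), or `NULL`.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids, species = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  sample_ids <- as.character(sample_ids)
  if (length(wavelengths) < 2) stopf("need at least 2 wavelengths")
  dw <- diff(wavelengths)
  if (any(dw <= 0)) stopf("wavelengths must be strictly increasing")
  if (max(dw) - min(dw) > 1e-9) {
    stopf("wavelength step is not uniform (spread %.3g nm)", max(dw) - min(dw))
  }
  if (ncol(absorbance) != length(wavelengths)) {
    stopf("absorbance has %d columns but there are %d wavelengths",
          ncol(absorbance), length(wavelengths))
  }
  if (nrow(absorbance) != length(sample_ids)) {
    stopf("absorbance has %d rows but there are %d sample ids",
          nrow(absorbance), length(sample_ids))
  }
  if (!all(is.finite(absorbance))) stopf("absorbance contains non-finite values")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != length(sample_ids)) {
      stopf("species must have one label per sample")
    }
  }
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         sample_ids = sample_ids, species = species),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.1f-%.1f nm, step %.3g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), diff(x$wavelengths[1:2])))
  if (!is.null(x$species)) {
    tab <- table(x$species)
    cat("  species:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param i sample indices, logical mask, or character ids.
#' @param ... unused.
#' @return a `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stopf("unknown sample id in subset")
  spectra_set(x$wavelengths, x$absorbance[i, , drop = FALSE],
              x$sample_ids[i], if (!is.null(x$species)) x$species[i])
}

#' Subset a spectra set by wavelength index
#'
#' Keeps a contiguous or strided selection of grid points; the result must
#' again be a uniform grid.
#'
#' @param s a `spectra_set`.
#' @param idx integer indices into the wavelength grid.
#' @return a `spectra_set` on the reduced grid.
#' @export
subset_wavelengths <- function(s, idx) {
  spectra_set(s$wavelengths[idx], s$absorbance[, idx, drop = FALSE],
              s$sample_ids, s$species)
}

#' Read spectra from delimited text
#'
#' Native dialect: CSV, first column the sample id, remaining column headers
#' the wavelengths in nm. One row per scan. An optional `species` column
#' (second position) carries the species label.
#'
#' @param path file path.
#' @param dialect format name; only `"csv"` is supported.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, dialect = "csv") {
  if (!identical(dialect, "csv")) stopf("unsupported spectra dialect: %s", dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stopf("ragged row %d in %s: %d fields, expected %d", bad, path, nf[bad], nf[1])
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  id_col <- names(df)[1]
  has_species <- length(df) >= 2 && identical(names(df)[2], "species")
  wl_cols <- names(df)[(2 + has_species):length(df)]
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) stopf("non-numeric wavelength header: %s", wl_cols[which(is.na(wl))[1]])
  if (any(diff(wl) <= 0)) stopf("wavelength header is not strictly increasing")
  vals <- as.matrix(df[wl_cols])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("non-numeric absorbance at row %d, wavelength %s in %s",
          bad[1], wl_cols[bad[2]], path)
  }
  spectra_set(wl, num, df[[id_col]],
              species = if (has_species) df[["species"]])
}

#' Write spectra in the native CSV dialect
#'
#' Values are written with 17 significant digits so a read/write/read round
#' trip is bit-exact.
#'
#' @param s a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c("sample_id",
              if (!is.null(s$species)) "species",
              sprintf("%.10g", s$wavelengths))
  writeLines(paste(header, collapse = ","), con)
  for (i in seq_along(s$sample_ids)) {
    row <- c(s$sample_ids[i],
             if (!is.null(s$species)) s$species[i],
             sprintf("%.17g", s$absorbance[i, ]))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Construct a reference table
#'
#' Wet-chemistry constituent concentrations in % of dry matter, one row per
#' sample. Missing values are `NA`, never silently zero. Values must lie in
#' `[0, 100]`; rows with `NDF < ADF` are retained with a warning (wet
#' chemistry can be noisy) since hemicellulose is defined as `NDF - ADF`.
#'
#' @param sample_ids unique character ids.
#' @param constituents data frame (or list) of numeric columns, %% DM.
#' @param species optional species label per sample.
#' @return a data frame of class `reference_table` with a `sample_id` column,
#'   one column per constituent, and optionally `species`.
#' @export
reference_table <- function(sample_ids, constituents, species = NULL) {
  sample_ids <- as.character(sample_ids)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  constituents <- as.data.frame(constituents)
  for (nm in names(constituents)) {
    v <- constituents[[nm]]
    if (!is.numeric(v)) stopf("constituent %s is not numeric", nm)
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stopf("constituent %s outside [0, 100] at row %d (value %g)", nm, bad[1], v[bad[1]])
    }
  }
  if (all(c("ndf", "adf") %in% names(constituents))) {
    both <- !is.na(constituents$ndf) & !is.na(constituents$adf)
    inv <- which(both & constituents$ndf < constituents$adf)
    if (length(inv)) {
      warnf("NDF < ADF for %d row(s) (first: %s); rows retained",
            length(inv), sample_ids[inv[1]])
    }
  }
  out <- cbind(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE), constituents)
  if (!is.null(species)) {
    if (length(species) != length(sample_ids)) stopf("species must match sample count")
    out$species <- as.character(species)
  }
  class(out) <- c("reference_table", "data.frame")
  out
}

ref_constituents <- function(ref) {
  setdiff(names(ref), c("sample_id", "species"))
}

#' Read a reference table from CSV
#'
#' Header must contain `sample_id` plus constituent columns (% DM) and an
#' optional `species` column. The missing-value sentinel (default `"NA"`)
#' is honored explicitly.
#'
#' @param path file path.
#' @param na the missing-value sentinel string(s).
#' @return a [reference_table()].
#' @export
read_reference <- function(path, na = "NA") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = na)
  if (!"sample_id" %in% names(df)) stopf("reference table needs a sample_id column")
  species <- df[["species"]]
  cols <- setdiff(names(df), c("sample_id", "species"))
  reference_table(df$sample_id, df[cols], species = species)
}

#' Write a reference table to CSV
#' @param ref a `reference_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate scans into one spectrum per sample
#'
#' Instrument practice scans each cup several times (three in the workflow
#' this package supports); the replicate spectra are averaged in absorbance
#' space before any analysis.
#'
#' @param s a `spectra_set` of individual scans.
#' @param groups named character vector mapping scan id -> sample id; every
#'   scan id of `s` must appear exactly once.
#' @return a `spectra_set` with one row per sample id, rows ordered by first
#'   appearance of each sample id in `groups`; each row is the arithmetic
#'   mean of its group's scans.
#' @export
average_replicates <- function(s, groups) {
  if (is.null(names(groups))) stopf("groups must be a named vector: scan id -> sample id")
  unknown <- setdiff(names(groups), s$sample_ids)
  if (length(unknown)) stopf("group references unknown scan id: %s", unknown[1])
  missing <- setdiff(s$sample_ids, names(groups))
  if (length(missing)) stopf("scan id not assigned to any group: %s", missing[1])
  out_ids <- unique(unname(groups))
  A <- matrix(0, length(out_ids), length(s$wavelengths))
  sp <- if (!is.null(s$species)) character(length(out_ids))
  for (j in seq_along(out_ids)) {
    scans <- names(groups)[groups == out_ids[j]]
    idx <- match(scans, s$sample_ids)
    A[j, ] <- colMeans(s$absorbance[idx, , drop = FALSE])
    if (!is.null(sp)) {
      u <- unique(s$species[idx])
      if (length(u) > 1) stopf("scans of sample %s have conflicting species labels", out_ids[j])
      sp[j] <- u
    }
  }
  spectra_set(s$wavelengths, A, out_ids, species = sp)
}
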