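#' Standard normal variate (SNV)
#'
#' Standardizes one spectrum to mean 0, SD 1 (population SD, divisor n).
#' Invariant under affine rescaling `a + b * row`, `b > 0`, which is what
#' makes it a scatter correction.
#'
#' @param row numeric spectrum, >= 2 points, non-constant.
#' @return the standardized spectrum.
#' @export
snv <- function(row) {
  if (length(row) < 2) stopf("snv needs at least 2 points")
  s <- sd_pop(row)
  if (s == 0) stopf("degenerate spectrum: constant row has no SNV transform")
  (row - mean(row)) / s
}

# least-squares polynomial baseline of `degree` in wavelength; returns residual
poly_residual <- function(row, wavelengths, degree) {
  x <- (wavelengths - mean(wavelengths)) / (diff(range(wavelengths)) / 2)
  B <- stats::poly(x, degree = degree, raw = FALSE)
  fit <- stats::lm.fit(cbind(1, B), row)
  fit$residuals
}

#' Detrend a spectrum
#'
#' Subtracts the least-squares polynomial baseline of the given degree
#' fitted over wavelength. The output is orthogonal to the polynomial
#' basis.
#'
#' @param row numeric spectrum.
#' @param wavelengths grid the row lives on.
#' @param degree 1 (line) or 2 (quadratic, the conventional detrend).
#' @return the detrended spectrum.
#' @export
detrend <- function(row, wavelengths, degree = 2) {
  stopifnot(degree %in% c(1, 2))
  if (length(row) <= degree + 1) stopf("spectrum too short to detrend at degree %d", degree)
  poly_residual(row, wavelengths, degree)
}

#' Fit multiplicative scatter correction state
#'
#' Stores the calibration-set mean spectrum; the weighted variant also
#' stores per-wavelength weights `1 / max(residual variance about the mean,
#' eps)`. State is fitted on calibration samples only and reused unchanged
#' for validation samples.
#'
#' @param calibration a `spectra_set` with >= 2 samples.
#' @param weighted logical; weighted MSC?
#' @param eps variance floor for the weights.
#' @return an object of class `scatter_state`.
#' @export
fit_msc <- function(calibration, weighted = FALSE, eps = 1e-10) {
  X <- calibration$absorbance
  if (nrow(X) < 2) stopf("MSC needs at least 2 calibration samples")
  m <- colMeans(X)
  w <- NULL
  if (weighted) {
    v <- colSums(sweep(X, 2, m)^2) / (nrow(X) - 1)
    w <- 1 / pmax(v, eps)
  }
  structure(list(type = if (weighted) "msc_weighted" else "msc_standard",
                 mean = m, weights = w, wavelengths = calibration$wavelengths),
            class = "scatter_state")
}

#' Apply multiplicative scatter correction to one spectrum
#'
#' Regresses the row on the stored mean spectrum with intercept (weighted
#' least squares for the weighted variant): `row ~ a + b * mean`, then
#' returns `(row - a) / b`.
#'
#' @param row numeric spectrum on the state's grid.
#' @param state a [fit_msc()] state.
#' @return the corrected spectrum.
#' @export
apply_msc <- function(row, state) {
  stopifnot(inherits(state, "scatter_state"))
  m <- state$mean
  if (length(row) != length(m)) stopf("grid mismatch: row has %d points, state %d", length(row), length(m))
  w <- state$weights %||% rep(1, length(m))
  sw <- sum(w)
  mw_m <- sum(w * m) / sw
  mw_r <- sum(w * row) / sw
  b <- sum(w * (m - mw_m) * (row - mw_r)) / sum(w * (m - mw_m)^2)
  if (!is.finite(b) || abs(b) < 1e-12) stopf("degenerate MSC regression: slope %g", b)
  a <- mw_r - b * mw_m
  (row - a) / b
}

#' Mean-scale then polynomially detrend a spectrum
#'
#' "Scale" pretreatment: divide the row by its own mean, then remove a
#' polynomial baseline of degree 1 (linear) or 2 (quadratic). Invariant
#' under positive rescaling of the row.
#'
#' @inheritParams detrend
#' @return the scaled, detrended spectrum.
#' @export
scale_polynomial <- function(row, wavelengths, degree = 1) {
  m <- mean(row)
  if (abs(m) < 1e-15) stopf("zero-mean row cannot be mean-scaled")
  detrend(row / m, wavelengths, degree)
}

#' Construct a math treatment
#'
#' WinISI-style 4-numeral math treatment: derivative order, gap (in data
#' points) over which the finite difference is taken, first running-average
#' (boxcar) width, and secondary smoothing width. `"0,0,1,1"` is the
#' identity. For derivative order 0 the gap is recorded but unused.
#'
#' @param derivative 0, 1 or 2.
#' @param gap points for the finite difference; >= 1 when derivative > 0.
#' @param smooth1 first boxcar width in points, >= 1.
#' @param smooth2 secondary boxcar width in points, >= 1.
#' @return an object of class `math_treatment`.
#' @export
math_treatment <- function(derivative, gap, smooth1 = 1, smooth2 = 1) {
  derivative <- as.integer(derivative); gap <- as.integer(gap)
  smooth1 <- as.integer(smooth1); smooth2 <- as.integer(smooth2)
  if (!derivative %in% 0:2) stopf("derivative order must be 0, 1 or 2")
  if (derivative > 0 && gap < 1) stopf("gap must be >= 1 for derivative treatments")
  if (gap < 0 || smooth1 < 1 || smooth2 < 1) stopf("invalid math treatment window")
  structure(list(derivative = derivative, gap = gap,
                 smooth1 = smooth1, smooth2 = smooth2),
            class = "math_treatment")
}

.scatter_labels <- c(none = "none", snv_only = "SNV", detrend_only = "DT",
                     snv_detrend = "SNV-DT", msc_standard = "MSC",
                     msc_weighted = "WMSC", scale_linear = "SCL",
                     scale_quadratic = "SCQ")

#' Construct a pretreatment
#'
#' A pretreatment pairs a math treatment with a scatter correction; it is
#' the unit of the pretreatment grid search. Serialized as the 4-numeral
#' string plus a scatter keyword, e.g. `"1,4,4,1+SNV"`.
#'
#' @param math a [math_treatment()] (or 4-element numeric vector).
#' @param scatter one of `"none"`, `"snv_only"`, `"detrend_only"`,
#'   `"snv_detrend"`, `"msc_standard"`, `"msc_weighted"`, `"scale_linear"`,
#'   `"scale_quadratic"`.
#' @return an object of class `pretreatment`.
#' @export
pretreatment <- function(math, scatter = "none") {
  if (is.numeric(math) && length(math) == 4) {
    math <- math_treatment(math[1], math[2], math[3], math[4])
  }
  stopifnot(inherits(math, "math_treatment"))
  scatter <- match.arg(scatter, names(.scatter_labels))
  structure(list(math = math, scatter = scatter), class = "pretreatment")
}

#' Serialize / parse a pretreatment string
#'
#' @param p a `pretreatment`.
#' @return `format_pretreatment`: the string form, e.g. `"1,4,4,1+SNV"`.
#' @export
format_pretreatment <- function(p) {
  stopifnot(inherits(p, "pretreatment"))
  sprintf("%d,%d,%d,%d+%s", p$math$derivative, p$math$gap,
          p$math$smooth1, p$math$smooth2, .scatter_labels[[p$scatter]])
}

#' @rdname format_pretreatment
#' @param s a string like `"1,4,4,1+SNV"`.
#' @return `parse_pretreatment`: the `pretreatment` object.
#' @export
parse_pretreatment <- function(s) {
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  if (length(parts) > 2) stopf("malformed pretreatment string: %s", s)
  nums <- suppressWarnings(as.integer(strsplit(parts[1], ",")[[1]]))
  if (length(nums) != 4 || anyNA(nums)) stopf("malformed math treatment in: %s", s)
  key <- if (length(parts) == 2) names(.scatter_labels)[match(parts[2], .scatter_labels)] else "none"
  if (is.na(key)) stopf("unknown scatter keyword in: %s", s)
  pretreatment(math_treatment(nums[1], nums[2], nums[3], nums[4]), key)
}

#' @export
print.pretreatment <- function(x, ...) {
  cat("<pretreatment>", format_pretreatment(x), "\n")
  invisible(x)
}

# boxcar running mean of width w on the columns of X (spectra in rows);
# returns list(X, keep): indices into the input grid that survived.
# For even widths the window extends one extra point forward.
boxcar_matrix <- function(X, w) {
  p <- ncol(X)
  if (w == 1) return(list(X = X, keep = seq_len(p)))
  lo <- (w - 1) %/% 2
  hi <- w - 1 - lo
  if (p - hi < 1 + lo) stopf("spectrum too short for smoothing window %d", w)
  keep <- (1 + lo):(p - hi)
  out <- matrix(0, nrow(X), length(keep))
  for (o in (-lo):hi) out <- out + X[, keep + o, drop = FALSE]
  list(X = out / w, keep = keep)
}

# gap derivative on the columns of X
gap_derivative_matrix <- function(X, order, gap) {
  p <- ncol(X)
  if (order == 0) return(list(X = X, keep = seq_len(p)))
  if (order == 1) {
    h <- ceiling(gap / 2)
    if (p - h < 1 + h) stopf("spectrum too short for gap %d first derivative", gap)
    keep <- (1 + h):(p - h)
    out <- X[, keep + h, drop = FALSE] - X[, keep - h, drop = FALSE]
  } else {
    g <- gap
    if (p - g < 1 + g) stopf("spectrum too short for gap %d second derivative", gap)
    keep <- (1 + g):(p - g)
    out <- X[, keep + g, drop = FALSE] - 2 * X[, keep, drop = FALSE] + X[, keep - g, drop = FALSE]
  }
  list(X = out, keep = keep)
}

#' Apply a math treatment to a spectra set
#'
#' Per row: first boxcar of width `smooth1`, then the gap derivative
#' (order 1: `y(i+h) - y(i-h)` with `h = ceiling(gap/2)`; order 2:
#' `y(i+g) - 2 y(i) + y(i-g)` with `g = gap`), then a boxcar of width
#' `smooth2`. Wavelengths whose windows are incomplete are trimmed, never
#' padded; the returned set carries the trimmed grid.
#'
#' @param s a `spectra_set`.
#' @param t a [math_treatment()].
#' @return a `spectra_set` on the trimmed grid.
#' @export
apply_math_treatment <- function(s, t) {
  stopifnot(inherits(s, "spectra_set"), inherits(t, "math_treatment"))
  st1 <- boxcar_matrix(s$absorbance, t$smooth1)
  wl <- s$wavelengths[st1$keep]
  st2 <- gap_derivative_matrix(st1$X, t$derivative, t$gap)
  wl <- wl[st2$keep]
  st3 <- boxcar_matrix(st2$X, t$smooth2)
  wl <- wl[st3$keep]
  spectra_set(wl, st3$X, s$sample_ids, s$species)
}

# apply the scatter step; returns list(set, state)
apply_scatter <- function(s, scatter, state = NULL, msc_eps = 1e-10) {
  X <- s$absorbance
  wl <- s$wavelengths
  if (scatter == "none") {
    state <- state %||% structure(list(type = "none"), class = "scatter_state")
    return(list(set = s, state = state))
  }
  if (scatter %in% c("msc_standard", "msc_weighted")) {
    if (is.null(state)) {
      state <- fit_msc(s, weighted = scatter == "msc_weighted", eps = msc_eps)
    }
    Y <- t(apply(X, 1, apply_msc, state = state))
  } else {
    state <- state %||% structure(list(type = scatter), class = "scatter_state")
    Y <- switch(scatter,
      snv_only = t(apply(X, 1, snv)),
      detrend_only = t(apply(X, 1, detrend, wavelengths = wl, degree = 2)),
      snv_detrend = t(apply(X, 1, function(r) detrend(snv(r), wl, 2))),
      scale_linear = t(apply(X, 1, scale_polynomial, wavelengths = wl, degree = 1)),
      scale_quadratic = t(apply(X, 1, scale_polynomial, wavelengths = wl, degree = 2)),
      stopf("unknown scatter correction: %s", scatter)
    )
  }
  list(set = spectra_set(wl, Y, s$sample_ids, s$species), state = state)
}

#' Apply a full pretreatment
#'
#' Scatter correction first (fitting MSC state on `s` if none is supplied,
#' in which case `s` must be the calibration set), then the math treatment.
#' The returned state is reused to process validation samples identically.
#'
#' @param s a `spectra_set`.
#' @param p a [pretreatment()].
#' @param state a `scatter_state` fitted on the calibration set, or `NULL`
#'   to fit one here.
#' @return list with `spectra` (transformed `spectra_set`, trimmed grid)
#'   and `state` (the `scatter_state`).
#' @export
apply_pretreatment <- function(s, p, state = NULL) {
  stopifnot(inherits(p, "pretreatment"))
  sc <- apply_scatter(s, p$scatter, state)
  list(spectra = apply_math_treatment(sc$set, p$math), state = sc$state)
}
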