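#' Default uniform wavelength grid
#'
#' The instrument range is 850-2500 nm scanned at 0.5 nm (3301 points). The
#' simulator defaults to a 2 nm step on the same range: the synthetic
#' absorption bands are >= 35 nm wide, so 2 nm sampling loses nothing while
#' keeping desk-scale runs fast.
#'
#' @param step grid step in nm.
#' @return numeric vector of wavelengths.
#' @export
default_wavelength_grid <- function(step = 2) seq(850, 2500, by = step)

#' Moment-matched truncated normal parameters
#'
#' Given a target mean/SD for the *truncated* distribution on `[lo, hi]`,
#' find the parent normal `(mu, sigma)` whose truncation has those moments,
#' so that generated compositions recover the published summary statistics
#' rather than being biased by asymmetric bounds.
#'
#' @param mean,sd target moments of the truncated distribution.
#' @param lo,hi truncation bounds, `lo < hi`.
#' @return list with `mu`, `sigma` of the parent normal.
#' @keywords internal
trunc_norm_match <- function(mean, sd, lo, hi) {
  if (!(lo < hi)) stopf("infeasible bounds: min %g >= max %g", lo, hi)
  if (sd < 0) stopf("SD must be >= 0")
  if (mean < lo || mean > hi) stopf("target mean %g outside bounds [%g, %g]", mean, lo, hi)
  if (sd == 0) return(list(mu = mean, sigma = 0))
  tn_moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    Z <- stats::pnorm(b) - stats::pnorm(a)
    if (Z < 1e-12) return(c(NA_real_, NA_real_))
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / Z
    v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mom <- tn_moments(par[1], exp(par[2]))
    if (anyNA(mom)) return(1e6)
    (mom[1] - mean)^2 / sd^2 + (mom[2] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# one inverse-CDF draw from the truncated parent; u in (0,1)
qtrunc_norm <- function(u, mu, sigma, lo, hi) {
  if (sigma == 0) return(rep(mu, length(u)))
  pa <- stats::pnorm(lo, mu, sigma); pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

#' Construct a simulation profile
#'
#' A profile fixes, per species, the mean/SD/bounds of each sampled
#' constituent (moisture, cp, adf, adl, hemicellulose; ndf is derived as
#' adf + hemicellulose), the scatter model, the noise level, and the seed.
#'
#' @param species species label.
#' @param mean,sd,min,max named numeric vectors over the sampled
#'   constituents, in %% DM.
#' @param slope_sd SD of the per-sample multiplicative scatter factor
#'   (around 1).
#' @param offset_sd SD of the per-sample additive baseline offset
#'   (absorbance units).
#' @param tilt_sd SD of the per-sample linear baseline tilt across the
#'   range (absorbance units).
#' @param noise_sd SD of the per-point Gaussian noise (absorbance units).
#' @param seed integer seed recorded in the profile.
#' @return an object of class `sim_profile`.
#' @export
simulation_profile <- function(species, mean, sd, min, max,
                               slope_sd = 0.1, offset_sd = 0.05,
                               tilt_sd = 0.02, noise_sd = 0.002,
                               seed = 1L) {
  wanted <- c("moisture", "cp", "adf", "adl", "hemicellulose")
  for (v in list(mean, sd, min, max)) {
    if (!all(wanted %in% names(v))) {
      stopf("profile vectors must name: %s", paste(wanted, collapse = ", "))
    }
  }
  if (any(sd[wanted] < 0)) stopf("SDs must be >= 0")
  if (any(min[wanted] >= max[wanted])) stopf("infeasible bounds: min >= max")
  if (any(c(slope_sd, offset_sd, tilt_sd, noise_sd) < 0)) stopf("scatter/noise SDs must be >= 0")
  structure(
    list(species = species,
         mean = mean[wanted], sd = sd[wanted], min = min[wanted], max = max[wanted],
         slope_sd = slope_sd, offset_sd = offset_sd, tilt_sd = tilt_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_profile"
  )
}

#' Built-in species composition profiles
#'
#' Mean, SD and range per constituent reproduce published wet-chemistry
#' descriptive statistics of corn stover and wheat straw calibration sets
#' (% DM). NDF is not listed: it is derived as ADF + hemicellulose.
#'
#' @param seed integer seed stored in the profile.
#' @param ... overrides passed to [simulation_profile()] (scatter and noise
#'   magnitudes).
#' @return a `sim_profile`.
#' @export
corn_stover_profile <- function(seed = 1L, ...) {
  simulation_profile(
    "corn_stover",
    mean = c(moisture = 5.35, cp = 5.18, adf = 36.28, adl = 3.26, hemicellulose = 27.78),
    sd   = c(moisture = 1.14, cp = 1.34, adf = 4.71, adl = 1.61, hemicellulose = 3.58),
    min  = c(moisture = 3.01, cp = 2.15, adf = 23.36, adl = 1.17, hemicellulose = 13.53),
    max  = c(moisture = 7.41, cp = 10.15, adf = 66.57, adl = 10.70, hemicellulose = 37.47),
    seed = seed, ...
  )
}

#' @rdname corn_stover_profile
#' @export
wheat_straw_profile <- function(seed = 1L, ...) {
  simulation_profile(
    "wheat_straw",
    mean = c(moisture = 4.62, cp = 3.36, adf = 46.79, adl = 6.92, hemicellulose = 30.58),
    sd   = c(moisture = 1.10, cp = 0.94, adf = 4.98, adl = 1.55, hemicellulose = 3.67),
    min  = c(moisture = 2.68, cp = 1.52, adf = 35.73, adl = 4.34, hemicellulose = 23.34),
    max  = c(moisture = 7.05, cp = 6.75, adf = 58.72, adl = 9.93, hemicellulose = 44.91),
    seed = seed, ...
  )
}

#' Draw synthetic compositions
#'
#' Moisture, CP, ADF, ADL and hemicellulose are drawn independently from
#' moment-matched truncated normals; NDF is set exactly to
#' ADF + hemicellulose so the fiber identity holds in synthetic truth;
#' ADL <= ADF is enforced by redrawing ADL. Each sample has its own
#' counter-indexed substream, so drawing more samples never perturbs
#' earlier ones.
#'
#' @param profile a [simulation_profile()].
#' @param n number of samples, >= 1.
#' @return a [reference_table()] with columns moisture, cp, ndf, adf, adl,
#'   hemicellulose and a species column.
#' @export
draw_compositions <- function(profile, n) {
  stopifnot(inherits(profile, "sim_profile"), n >= 1)
  vars <- names(profile$mean)
  pars <- lapply(vars, function(v) {
    c(trunc_norm_match(profile$mean[[v]], profile$sd[[v]],
                       profile$min[[v]], profile$max[[v]]),
      lo = profile$min[[v]], hi = profile$max[[v]])
  })
  names(pars) <- vars
  draw_one <- function(i) {
    set.seed(substream_seed(profile$seed, "compose", i))
    x <- vapply(vars, function(v) {
      p <- pars[[v]]
      qtrunc_norm(stats::runif(1), p$mu, p$sigma, p$lo, p$hi)
    }, numeric(1))
    tries <- 0
    while (x[["adl"]] > x[["adf"]] && tries < 100) {
      p <- pars[["adl"]]
      x[["adl"]] <- qtrunc_norm(stats::runif(1), p$mu, p$sigma, p$lo, p$hi)
      tries <- tries + 1
    }
    if (x[["adl"]] > x[["adf"]]) x[["adl"]] <- x[["adf"]]
    x
  }
  draws <- t(vapply(seq_len(n), draw_one, numeric(length(vars))))
  colnames(draws) <- vars
  out <- as.data.frame(draws)
  out$ndf <- out$adf + out$hemicellulose
  out <- out[, c("moisture", "cp", "ndf", "adf", "adl", "hemicellulose")]
  reference_table(sprintf("%s_%04d", profile$species, seq_len(n)), out,
                  species = rep(profile$species, n))
}

#' Build a constituent absorptivity library
#'
#' Each constituent's absorptivity curve is a positive sum of Gaussian bands
#' (center nm, width nm = Gaussian sigma, amplitude = absorbance per unit %
#' concentration), evaluated on the target grid. Curves must be pairwise
#' non-proportional (cosine similarity < 0.999) so the regression problem
#' is identifiable.
#'
#' @param bands named list: constituent -> data frame with columns `center`,
#'   `width`, `amplitude`.
#' @param grid wavelength grid (nm), uniform and increasing.
#' @return an object of class `component_library`: list with `wavelengths`
#'   and a `curves` matrix (one column per constituent).
#' @export
make_component_library <- function(bands, grid) {
  if (any(diff(grid) <= 0)) stopf("grid must be increasing")
  curves <- vapply(names(bands), function(nm) {
    b <- as.data.frame(bands[[nm]])
    stopifnot(all(c("center", "width", "amplitude") %in% names(b)))
    if (any(b$center < min(grid) | b$center > max(grid))) {
      stopf("band center outside grid span for constituent %s", nm)
    }
    if (any(b$width <= 0) || any(b$amplitude < 0)) {
      stopf("band widths must be > 0 and amplitudes >= 0 (constituent %s)", nm)
    }
    rowSums(vapply(seq_len(nrow(b)), function(i) {
      b$amplitude[i] * exp(-0.5 * ((grid - b$center[i]) / b$width[i])^2)
    }, numeric(length(grid))))
  }, numeric(length(grid)))
  nm <- colnames(curves)
  for (i in seq_along(nm)) {
    for (j in seq_len(i - 1)) {
      cs <- sum(curves[, i] * curves[, j]) /
        sqrt(sum(curves[, i]^2) * sum(curves[, j]^2))
      if (cs >= 0.999) {
        stopf("constituents %s and %s have near-proportional curves (cos %.5f); not identifiable",
              nm[j], nm[i], cs)
      }
    }
  }
  structure(list(wavelengths = grid, curves = curves), class = "component_library")
}

#' Default six-constituent band library
#'
#' Each constituent absorbs at chemically motivated, mutually distinct
#' centers — water O-H (1450/1940 nm), protein N-H and C=O combination
#' bands (1510/2055/2180 nm), carbohydrate C-H/O-H (1730/2100/2345 nm),
#' cellulose (1490/2110/2450 nm), lignin aromatics (1685/2270/2440 nm),
#' xylan (1925/2090/2460 nm) — so the mixture problem is well conditioned,
#' while the *average* spectrum still shows the five main straw absorption
#' peaks near 1450, 1900, 2100, 2300 and 2450 nm (the last an edge band so
#' its full Gaussian fits inside the 850-2500 nm scan). Amplitudes are
#' scaled so a typical composition yields peak absorbance around 0.5-1, as
#' in ground-straw log(1/R) spectra.
#'
#' @param grid wavelength grid, default [default_wavelength_grid()].
#' @return a `component_library` with the six constituent curves.
#' @export
default_band_library <- function(grid = default_wavelength_grid()) {
  bands <- list(
    moisture = data.frame(center = c(1450, 1940),
                          width = c(45, 55), amplitude = c(0.020, 0.026)),
    cp = data.frame(center = c(1510, 2055, 2180),
                    width = c(40, 45, 40), amplitude = c(0.004, 0.008, 0.006)),
    ndf = data.frame(center = c(1730, 2100, 2345),
                     width = c(50, 60, 45), amplitude = c(0.0020, 0.0040, 0.0030)),
    adf = data.frame(center = c(1490, 2110, 2450),
                     width = c(60, 50, 60), amplitude = c(0.0015, 0.0030, 0.0040)),
    adl = data.frame(center = c(1685, 2270, 2440),
                     width = c(35, 40, 45), amplitude = c(0.0030, 0.0050, 0.0020)),
    hemicellulose = data.frame(center = c(1925, 2090, 2460),
                               width = c(45, 35, 70), amplitude = c(0.0015, 0.0050, 0.0030))
  )
  make_component_library(bands, grid)
}

#' Simulate absorbance spectra from compositions
#'
#' Beer-Lambert forward model with per-sample scatter: each spectrum is
#' `b_i * sum_c conc_ic * curve_c(lambda) + a_i + t_i * (lambda - mid)/span
#' + noise`, with multiplicative factor `b_i ~ N(1, slope_sd)`, offset
#' `a_i ~ N(0, offset_sd)`, tilt `t_i ~ N(0, tilt_sd)` and iid Gaussian
#' noise. Deterministic under the profile seed; per-sample substreams make
#' the first `n` spectra invariant to adding more.
#'
#' @param ref a [reference_table()]; its constituents must all appear in
#'   the library.
#' @param lib a [make_component_library()] result.
#' @param profile a [simulation_profile()] supplying scatter/noise
#'   magnitudes and the seed.
#' @return a `spectra_set` on the library grid.
#' @export
simulate_spectra <- function(ref, lib, profile) {
  stopifnot(inherits(lib, "component_library"), inherits(profile, "sim_profile"))
  cons <- ref_constituents(ref)
  missing_c <- setdiff(cons, colnames(lib$curves))
  if (length(missing_c)) stopf("library lacks curve(s) for: %s", paste(missing_c, collapse = ", "))
  C <- as.matrix(as.data.frame(ref)[cons])
  if (anyNA(C)) stopf("cannot simulate spectra from missing concentrations")
  wl <- lib$wavelengths
  mid <- (min(wl) + max(wl)) / 2
  span <- max(wl) - min(wl)
  tilt_basis <- (wl - mid) / span
  clean <- C %*% t(lib$curves[, cons, drop = FALSE])
  n <- nrow(clean)
  A <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    set.seed(substream_seed(profile$seed, "scatter", i))
    b <- stats::rnorm(1, 1, profile$slope_sd)
    a <- stats::rnorm(1, 0, profile$offset_sd)
    tl <- stats::rnorm(1, 0, profile$tilt_sd)
    set.seed(substream_seed(profile$seed, "noise", i))
    eps <- stats::rnorm(length(wl), 0, profile$noise_sd)
    A[i, ] <- b * clean[i, ] + a + tl * tilt_basis + eps
  }
  spectra_set(wl, A, ref$sample_id, species = ref$species)
}

#' Simulate a full species data set
#'
#' Convenience wrapper: draws `n` compositions from the profile and
#' simulates their spectra with the default band library.
#'
#' @param profile a [simulation_profile()].
#' @param n samples to generate.
#' @param grid wavelength grid.
#' @param lib optional `component_library`; default [default_band_library()].
#' @return list with `spectra` (a `spectra_set`) and `reference`
#'   (a `reference_table`).
#' @export
simulate_species <- function(profile, n, grid = default_wavelength_grid(),
                             lib = default_band_library(grid)) {
  ref <- draw_compositions(profile, n)
  list(spectra = simulate_spectra(ref, lib, profile), reference = ref)
}
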