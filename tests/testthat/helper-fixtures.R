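# Shared fixtures and independent oracles.

# tiny deterministic spectra set: smooth curves plus per-sample offsets
tiny_spectra <- function(n = 6, p = 40, seed = 11, species = NULL) {
  set.seed(seed)
  wl <- seq(1000, 1000 + 2 * (p - 1), by = 2)
  base <- exp(-0.5 * ((wl - mean(wl)) / (p / 3))^2)
  A <- t(vapply(seq_len(n), function(i) {
    (0.8 + 0.1 * i / n) * base + 0.01 * i + rnorm(p, 0, 0.001)
  }, numeric(p)))
  spectra_set(wl, A, sprintf("s%02d", seq_len(n)), species = species)
}

# Independent PLS1 oracle: the fitted values of k-factor PLS1 are the
# least-squares projection of y onto X_c times the Krylov space
# K_k(X'X, X'y). Built by Arnoldi orthogonalization, so it shares no code
# path (and no deflation) with fit_mpls.
pls1_krylov <- function(X, y, k) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  C <- crossprod(Xc)
  s <- drop(crossprod(Xc, yc))
  V <- matrix(0, ncol(X), k)
  v <- s / sqrt(sum(s^2))
  for (j in seq_len(k)) {
    V[, j] <- v
    v <- drop(C %*% v)
    for (jj in seq_len(j)) v <- v - sum(v * V[, jj]) * V[, jj]
    for (jj in seq_len(j)) v <- v - sum(v * V[, jj]) * V[, jj]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
  }
  G <- crossprod(V, C %*% V)
  beta <- drop(V %*% solve(G, crossprod(V, s)))
  list(
    fitted = mean(y) + drop(Xc %*% beta),
    predict = function(Xnew) {
      mean(y) + drop(sweep(as.matrix(Xnew), 2, colMeans(X)) %*% beta)
    }
  )
}

# clean linear-mixture data set for recovery checks
noiseless_species <- function(n = 30, seed = 5, step = 8) {
  prof <- corn_stover_profile(seed = seed, slope_sd = 0, offset_sd = 0,
                              tilt_sd = 0, noise_sd = 0)
  simulate_species(prof, n, grid = default_wavelength_grid(step))
}

expect_rounds_to <- function(x, printed, digits) {
  expect_equal(round(x, digits), printed, tolerance = 1e-12)
}
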