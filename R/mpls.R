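#' Fit a modified partial least squares (MPLS) regression
#'
#' PLS1 by NIPALS deflation with an optional modification: after each
#' factor is extracted, the spectral residuals at each wavelength are
#' divided by their standard deviation before the next factor is computed.
#' The per-factor scale vectors are stored and replayed at prediction time.
#' With `standardize_residuals = FALSE` the procedure is exactly PLS1.
#'
#' @param X numeric matrix of pretreated spectra, one row per sample.
#' @param y numeric response (constituent concentration, %% DM).
#' @param max_factors maximum latent factors (default 16); truncated with a
#'   warning if it exceeds the effective rank.
#' @param standardize_residuals logical; apply the per-factor residual
#'   standardization (the "modified" in MPLS)?
#' @param sd_floor floor applied to residual SDs before division, so
#'   perfectly fitted wavelengths do not blow up.
#' @param pretreatment_string optional label recording the pretreatment the
#'   model was trained under.
#' @return an object of class `mpls_model` with centering vectors,
#'   per-factor weights/loadings/y-loadings/scale vectors, the composed
#'   coefficient vector, and `chosen_factors` (initially the fitted count;
#'   [cross_validate()] refines it).
#' @export
fit_mpls <- function(X, y, max_factors = 16, standardize_residuals = TRUE,
                     sd_floor = 1e-12, pretreatment_string = NA_character_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("X has %d rows but y has %d values", n, length(y))
  if (!all(is.finite(y)) || !all(is.finite(X))) stopf("X and y must be finite")
  if (stats::var(y) == 0) stopf("zero-variance response")
  if (n < max_factors + 2) {
    warnf("max_factors %d too large for n = %d; truncating to %d",
          max_factors, n, n - 2)
    max_factors <- n - 2
  }
  if (max_factors < 1) stopf("need at least 3 samples")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xr <- sweep(X, 2, x_mean)
  yr <- y - y_mean
  W <- matrix(0, p, max_factors)   # weights
  P <- matrix(0, p, max_factors)   # x loadings
  q <- numeric(max_factors)        # y loadings
  S <- matrix(1, p, max_factors)   # residual scale vectors
  k <- 0
  for (f in seq_len(max_factors)) {
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yr^2)))) {
      warnf("rank exhausted after %d factor(s); truncating", k)
      break
    }
    w <- w / nw
    tt <- drop(Xr %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-24) { warnf("rank exhausted after %d factor(s); truncating", k); break }
    pl <- drop(crossprod(Xr, tt)) / t2
    ql <- sum(tt * yr) / t2
    Xr <- Xr - tcrossprod(tt, pl)
    yr <- yr - ql * tt
    W[, f] <- w; P[, f] <- pl; q[f] <- ql
    k <- f
    if (standardize_residuals) {
      s_f <- col_sds(Xr, floor_at = sd_floor)
      Xr <- sweep(Xr, 2, s_f, "/")
      S[, f] <- s_f
    }
  }
  if (k == 0) stopf("no usable factor could be extracted")
  W <- W[, seq_len(k), drop = FALSE]
  P <- P[, seq_len(k), drop = FALSE]
  q <- q[seq_len(k)]
  S <- S[, seq_len(k), drop = FALSE]
  m <- structure(
    list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
         y_loadings = q, scales = S, standardize = standardize_residuals,
         n_factors = k, chosen_factors = k,
         pretreatment = pretreatment_string),
    class = "mpls_model"
  )
  m$coefficients <- mpls_coefficients(m, k)
  m
}

# composed coefficient vector for k factors, by reverse accumulation of the
# per-factor linear replay (deflation then scaling): yhat - y_mean =
# (x - x_mean) %*% beta.
mpls_coefficients <- function(m, k = m$chosen_factors) {
  p <- length(m$x_mean)
  g <- numeric(p)
  for (f in rev(seq_len(k))) {
    h <- if (m$standardize) g / m$scales[, f] else g
    g <- m$y_loadings[f] * m$weights[, f] + h -
      m$weights[, f] * sum(m$loadings[, f] * h)
  }
  g
}

#' Predict from an MPLS model
#'
#' Applies the stored centering, then replays the per-factor
#' score/deflation/scaling sequence of the fitted model on the new spectra.
#'
#' @param object an `mpls_model`.
#' @param X pretreated spectra matrix on the model's (trimmed) grid.
#' @param k number of factors to use; defaults to `chosen_factors`; `k = 0`
#'   returns the training mean for every row.
#' @param all_k logical; if `TRUE` return an `n x (n_factors + 1)` matrix of
#'   predictions at 0..n_factors factors instead of a vector.
#' @param ... unused.
#' @return numeric predictions, one per row of `X` (or a matrix when
#'   `all_k`).
#' @export
predict.mpls_model <- function(object, X, k = NULL, all_k = FALSE, ...) {
  m <- object
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_mean)) {
    stopf("grid mismatch: model expects %d wavelengths, got %d",
          length(m$x_mean), ncol(X))
  }
  k <- k %||% m$chosen_factors
  if (k > m$n_factors) stopf("k = %d exceeds the %d stored factors", k, m$n_factors)
  Xr <- sweep(X, 2, m$x_mean)
  preds <- matrix(m$y_mean, nrow(X), m$n_factors + 1)
  acc <- rep(m$y_mean, nrow(X))
  for (f in seq_len(m$n_factors)) {
    tt <- drop(Xr %*% m$weights[, f])
    acc <- acc + m$y_loadings[f] * tt
    preds[, f + 1] <- acc
    Xr <- Xr - tcrossprod(tt, m$loadings[, f])
    if (m$standardize) Xr <- sweep(Xr, 2, m$scales[, f], "/")
  }
  if (all_k) preds else preds[, k + 1]
}

#' @export
print.mpls_model <- function(x, ...) {
  cat(sprintf("<mpls_model> %d factors fitted (chosen %d), %d wavelengths%s%s\n",
              x$n_factors, x$chosen_factors, length(x$x_mean),
              if (x$standardize) ", residual-standardized" else " (plain PLS1)",
              if (is.na(x$pretreatment)) "" else paste0(", pretreatment ", x$pretreatment)))
  invisible(x)
}

#' Grouped cross-validation for factor selection
#'
#' Samples are assigned to groups by a seeded shuffle followed by
#' round-robin allocation (so sorted calibration sets do not confound folds
#' with concentration). For each held-out group the model is fitted on the
#' remainder and the group predicted at every factor count;
#' `SECV(k) = sqrt(sum(e_cv^2) / n)`. The chosen factor count is the
#' smallest `k` whose SECV is within `tolerance` of the minimum (parsimony
#' rule; strict argmin overfits the factor count on small n).
#'
#' @inheritParams fit_mpls
#' @param groups number of CV groups (default 4).
#' @param seed integer seed for the group shuffle.
#' @param tolerance parsimony multiplier on the minimum SECV (default 1.02).
#' @return an object of class `cv_result`: `secv` (vector over factor
#'   counts 1..max), `chosen_factors`, `cv_predictions` (per sample, at the
#'   chosen count), `group` assignment.
#' @export
cross_validate <- function(X, y, groups = 4, max_factors = 16, seed = 1,
                           standardize_residuals = TRUE, tolerance = 1.02) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (groups < 2) stopf("need at least 2 CV groups")
  if (n < 2 * groups) stopf("need n >= 2 * groups (n = %d, groups = %d)", n, groups)
  set.seed(substream_seed(seed, "cv"))
  perm <- sample.int(n)
  grp <- integer(n)
  grp[perm] <- ((seq_len(n) - 1) %% groups) + 1
  largest_group <- max(table(factor(grp, levels = seq_len(groups))))
  kmax <- min(max_factors, n - largest_group - 2)
  preds <- matrix(NA_real_, n, kmax + 1)
  for (g in seq_len(groups)) {
    hold <- grp == g
    fit <- suppressWarnings(fit_mpls(X[!hold, , drop = FALSE], y[!hold],
                                     max_factors = kmax,
                                     standardize_residuals = standardize_residuals))
    pk <- predict(fit, X[hold, , drop = FALSE], all_k = TRUE)
    preds[hold, seq_len(ncol(pk))] <- pk
    if (ncol(pk) < ncol(preds)) {  # fold hit rank limit; pad with its last column
      preds[hold, (ncol(pk) + 1):ncol(preds)] <- pk[, ncol(pk)]
    }
  }
  secv <- sqrt(colMeans((preds[, -1, drop = FALSE] - y)^2))
  chosen <- which(secv <= tolerance * min(secv))[1]
  structure(
    list(secv = secv, chosen_factors = chosen,
         cv_predictions = preds[, chosen + 1], group = grp, seed = seed,
         tolerance = tolerance),
    class = "cv_result"
  )
}

#' Serialize / restore an MPLS model as JSON
#'
#' All vectors and scalars (centering, weights, loadings, scale vectors,
#' coefficients, pretreatment string) are written with full precision so a
#' reloaded model predicts bit-identically.
#'
#' @param m an `mpls_model`.
#' @param path file to write.
#' @return `path` invisibly; `model_from_json` returns the `mpls_model`.
#' @export
model_to_json <- function(m, path) {
  stopifnot(inherits(m, "mpls_model"))
  # doubles go through %.17g strings so the decimal text round-trips bit-exactly
  enc <- function(x) sprintf("%.17g", x)
  enc_mat <- function(M) lapply(seq_len(ncol(M)), function(j) enc(M[, j]))
  obj <- list(
    x_mean = enc(m$x_mean), y_mean = enc(m$y_mean),
    weights = enc_mat(m$weights),
    loadings = enc_mat(m$loadings),
    y_loadings = enc(m$y_loadings),
    scales = enc_mat(m$scales),
    standardize = m$standardize,
    n_factors = m$n_factors, chosen_factors = m$chosen_factors,
    coefficients = enc(m$coefficients), pretreatment = m$pretreatment
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(x) as.numeric(unlist(x, use.names = FALSE))
  dec_mat <- function(cols) do.call(cbind, lapply(cols, dec))
  m <- structure(
    list(x_mean = dec(obj$x_mean), y_mean = dec(obj$y_mean),
         weights = dec_mat(obj$weights), loadings = dec_mat(obj$loadings),
         y_loadings = dec(obj$y_loadings), scales = dec_mat(obj$scales),
         standardize = isTRUE(obj$standardize),
         n_factors = as.integer(obj$n_factors),
         chosen_factors = as.integer(obj$chosen_factors),
         coefficients = dec(obj$coefficients),
         pretreatment = obj$pretreatment %||% NA_character_),
    class = "mpls_model"
  )
  m
}
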