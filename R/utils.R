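#' @keywords internal
"_PACKAGE"

# Named substreams keep every stage's randomness independent of the others:
# re-seeding one stage (or adding samples to the generator) never perturbs
# draws made elsewhere.
.stream_ids <- c(
  compose = 1L, scatter = 2L, noise = 3L,
  cv = 4L, gh = 5L, screen = 6L, split = 7L, simulate = 8L
)

#' Derive a deterministic sub-seed from a base seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Each operation draws from its own named substream, and per-sample draws
#' additionally index a counter, so generating `n + k` samples reproduces
#' the first `n` exactly.
#'
#' @param seed base integer seed.
#' @param stream substream name (compose, scatter, noise, cv, gh, screen,
#'   split, simulate).
#' @param counter non-negative integer counter (e.g. sample index).
#' @return an integer seed in `[1, 2^31 - 19]`.
#' @keywords internal
substream_seed <- function(seed, stream, counter = 0L) {
  sid <- .stream_ids[[stream]]
  if (is.null(sid)) stop("unknown substream: ", stream)
  # all intermediate products stay well below 2^53, so double arithmetic is exact
  s <- ((seed %% 65521) * 31771 + sid * 131071 + counter * 7919) %% 2147483629
  as.integer(s + 1)
}

# population SD (divisor n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# column SDs with divisor n - 1, floored
col_sds <- function(X, floor_at = 0) {
  s <- sqrt(colSums(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1))
  pmax(s, floor_at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Constituents handled by the workflow
#' @return character vector of the six constituent names, in reporting order.
#' @export
constituent_names <- function() {
  c("moisture", "cp", "ndf", "adf", "adl", "hemicellulose")
}
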