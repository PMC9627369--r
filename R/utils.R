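# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a root seed and a label
#'
#' All stochastic stages of the pipeline draw their RNG state from a single
#' root seed through this function, so that permutation, bootstrap, and
#' per-subject simulation streams are mutually independent and reproducible
#' regardless of execution order. The hash is a 31-bit polynomial fold, so
#' the result is always a valid argument to [set.seed()].
#'
#' @param root integer root seed.
#' @param label character label naming the consumer stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, label = "") {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  m <- 2147483647
  h <- abs(as.double(root)) %% m
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Truncated-normal draws by inverse-CDF; exact for the moderate truncations
# used by the cohort generator.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(n, rho = 0.3) {
  stopifnot(n >= 1, abs(rho) < 1)
  innov <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- innov[1]
  if (n > 1) {
    sc <- sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1] + sc * innov[t]
  }
  x
}

# voxel coordinates (1-based) of linear indices in a 3D grid
voxel_coords <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(
    idx0 %% dims[1] + 1L,
    (idx0 %/% dims[1]) %% dims[2] + 1L,
    idx0 %/% (dims[1] * dims[2]) + 1L
  )
}

# squared Euclidean distance (in voxel units) from every grid voxel to a point
grid_dist2 <- function(dims, centre) {
  dx <- (seq_len(dims[1]) - centre[1])^2
  dy <- (seq_len(dims[2]) - centre[2])^2
  dz <- (seq_len(dims[3]) - centre[3])^2
  outer(outer(dx, dy, `+`), dz, `+`)
}
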