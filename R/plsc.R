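# Behavioural PLS correlation: SVD of the cross-block correlation,
# permutation significance, bootstrap ratios and loading CIs.

#' Residualize a matrix on nuisance covariates
#'
#' Replaces every column of `M` by its least-squares residual on
#' `[intercept, nuisance]`. Residual columns are exactly orthogonal to
#' every nuisance column. With no nuisance supplied the result is the
#' column-centred input.
#'
#' @param M subjects x columns numeric matrix.
#' @param nuisance subjects x covariates numeric matrix (rows aligned).
#' @return residual matrix of the same shape.
#' @export
residualize <- function(M, nuisance = NULL) {
  M <- as.matrix(M)
  X <- cbind(intercept = rep(1, nrow(M)), nuisance)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    piv <- qx$pivot[seq_len(qx$rank)]
    bad <- setdiff(colnames(X), colnames(X)[piv])
    stop("rank-deficient nuisance matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  out <- qr.resid(qx, M)
  dimnames(out) <- dimnames(M)
  out
}

# column SDs (denominator n - 1) without an apply loop
.colsds <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sqrt(pmax(colSums(M^2) - n * mu^2, 0) / (n - 1))
}

# z-score columns with sd denominator n - 1; errors on zero variance
.zscore <- function(M, what = "matrix") {
  n <- nrow(M)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = n)
  sds <- sqrt(pmax(colSums(Mc^2), 0) / (n - 1))
  if (any(sds == 0) || anyNA(sds)) {
    bad <- which(sds == 0 | is.na(sds))
    nm <- colnames(M)[bad] %||% as.character(bad)
    stop("zero-variance column(s) in ", what, ": ", paste(nm, collapse = ", "))
  }
  Mc / rep(sds, each = n)
}

#' Fit the PLS correlation decomposition
#'
#' Columns of the imaging block `X` (subjects x voxels) and behaviour
#' block `Y` (subjects x behaviours) are z-scored; the cross-block
#' correlation `R = Y_z' X_z / (n - 1)` is decomposed as `R = U S V'`.
#' Each latent variable (LV) pairs a behavioural salience column of `U`
#' with an imaging salience column of `V`; covariance explained is
#' `s_i^2 / sum s_j^2`. Composite scores are `X_z V` (imaging) and
#' `Y_z U` (behavioural). Sign convention: the largest-magnitude element
#' of each `U` column is made positive (flipping `U` and `V` together),
#' so results are invariant to the SVD's arbitrary sign.
#'
#' @param X subjects x voxels matrix (no missing values).
#' @param Y subjects x behaviours matrix (no missing values).
#' @return object of class `plsc_result` with `singular_values`,
#'   `cov_explained`, `u` (behavioural saliences), `v` (imaging
#'   saliences), `imaging_scores`, `behavioral_scores`, and per-LV
#'   `score_correlation`.
#' @export
plsc_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n < max(3, ncol(Y) + 1)) {
    stop("need at least max(3, behaviours + 1) subjects")
  }
  if (anyNA(X) || anyNA(Y)) stop("missing values in PLS blocks")
  Xz <- .zscore(X, "X (imaging block)")
  Yz <- .zscore(Y, "Y (behaviour block)")
  R <- crossprod(Yz, Xz) / (n - 1)
  sv <- svd(R)
  U <- sv$u; V <- sv$v; d <- sv$d
  for (i in seq_along(d)) {
    j <- which.max(abs(U[, i]))
    if (U[j, i] < 0) { U[, i] <- -U[, i]; V[, i] <- -V[, i] }
  }
  rownames(U) <- colnames(Y); rownames(V) <- colnames(X)
  xs <- Xz %*% V
  ys <- Yz %*% U
  structure(
    list(singular_values = d,
         cov_explained = d^2 / sum(d^2),
         u = U, v = V,
         imaging_scores = xs, behavioral_scores = ys,
         score_correlation = vapply(seq_along(d), function(i) {
           stats::cor(xs[, i], ys[, i])
         }, 0),
         n = n),
    class = "plsc_result"
  )
}

#' @export
print.plsc_result <- function(x, ...) {
  k <- min(5, length(x$singular_values))
  cat("PLS correlation fit (n =", x$n, "):\n")
  for (i in seq_len(k)) {
    cat(sprintf("  LV-%d  s = %.4f  cov explained = %.1f%%  score r = %.2f\n",
                i, x$singular_values[i], 100 * x$cov_explained[i],
                x$score_correlation[i]))
  }
  invisible(x)
}

# singular values of the cross-correlation of pre-z-scored blocks
.plsc_singvals <- function(Xz, Yz) {
  svd(crossprod(Yz, Xz) / (nrow(Xz) - 1), nu = 0, nv = 0)$d
}

#' Permutation test for latent-variable significance
#'
#' Rows of `Y` are permuted as a block (`X` fixed) and the decomposition
#' recomputed; each permuted singular value is compared with the observed
#' one at the same LV position (no rotation). The p value is
#' `(1 + #\{s_perm >= s_obs\}) / (1 + n_perm)`.
#'
#' @param X,Y the PLS blocks.
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   draws a warning).
#' @param seed integer seed; the permutation stream is derived from it
#'   and independent of the bootstrap stream.
#' @return list with `perm_p` per LV and the `perm_singvals` matrix.
#' @export
permutation_test <- function(X, Y, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p value")
  obs <- plsc_fit(X, Y)
  n <- nrow(as.matrix(X))
  Xz <- .zscore(as.matrix(X)); Yz <- .zscore(as.matrix(Y))
  set.seed(derive_seed(seed, "permutation"))
  k <- length(obs$singular_values)
  perm_d <- matrix(0, n_perm, k)
  for (b in seq_len(n_perm)) {
    perm_d[b, ] <- .plsc_singvals(Xz, Yz[sample.int(n), , drop = FALSE])
  }
  cnt <- colSums(perm_d >= matrix(obs$singular_values, n_perm, k, byrow = TRUE))
  list(perm_p = (1 + cnt) / (1 + n_perm), perm_singvals = perm_d)
}

# Procrustes rotation aligning a resampled U to the observed U
.procrustes_rotation <- function(U_obs, U_boot) {
  s <- svd(crossprod(U_obs, U_boot))
  tcrossprod(s$v, s$u)   # Q such that U_boot %*% Q ~ U_obs
}

#' Bootstrap inference for saliences and behavioural loadings
#'
#' Subjects are resampled with replacement (X and Y rows paired); each
#' resample's decomposition is aligned to the observed one by Procrustes
#' rotation of the behavioural saliences. Voxel bootstrap ratios are
#' computed on the singular-value-weighted saliences (`V S`), the scale
#' on which the ratio is approximately standard normal under the null:
#' `BSR_v = (v s)_obs / SD_boot(v s)`, capped at `bsr_cap` where the
#' bootstrap SD collapses to (near) zero; voxels with
#' `|BSR| > bsr_threshold` (default 3.3, a two-sided normal tail of
#' about 0.001) are flagged.
#' The behavioural loading of score `b` on LV `i` is the Pearson
#' correlation between `Y[, b]` and the LV's imaging composite score,
#' recomputed in every resample; its 95% percentile CI flags the loading
#' significant when it excludes zero. Resamples in which a column loses
#' all variance are redrawn (at most `max_redraw` times each).
#'
#' @param X,Y the PLS blocks.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed (bootstrap stream derived independently).
#' @param bsr_threshold voxel reliability threshold on `|BSR|`.
#' @param bsr_cap cap for zero-SD degeneracies.
#' @param conf CI level for the loadings.
#' @param max_redraw maximal redraws per degenerate resample.
#' @return list with `bootstrap_ratios` (voxels x LVs), `boot_sd`,
#'   `bsr_significant`, `loadings`, `loading_ci_lower`,
#'   `loading_ci_upper`, `loading_significant` (behaviours x LVs), and
#'   `n_redraws`.
#' @export
bootstrap_inference <- function(X, Y, n_boot = 1000, seed = 1L,
                                bsr_threshold = 3.3, bsr_cap = 1e6,
                                conf = 0.95, max_redraw = 50) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n >= 10)
  obs <- plsc_fit(X, Y)
  k <- length(obs$singular_values)
  nv <- ncol(X); nb <- ncol(Y)
  set.seed(derive_seed(seed, "bootstrap"))

  v_boot <- array(NA_real_, c(nv, k, n_boot))
  load_boot <- array(NA_real_, c(nb, k, n_boot))
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    for (try in seq_len(max_redraw + 1L)) {
      idx <- sample.int(n, replace = TRUE)
      ok <- all(.colsds(X[idx, , drop = FALSE]) > 0) &&
        all(.colsds(Y[idx, , drop = FALSE]) > 0)
      if (ok) break
      n_redraws <- n_redraws + 1L
      if (try > max_redraw) stop("too many degenerate bootstrap resamples")
    }
    Xb <- .zscore(X[idx, , drop = FALSE])
    Yb <- .zscore(Y[idx, , drop = FALSE])
    sv <- svd(crossprod(Yb, Xb) / (n - 1))
    Q <- .procrustes_rotation(obs$u, sv$u[, seq_len(k), drop = FALSE])
    Vb <- sv$v[, seq_len(k), drop = FALSE] %*% Q
    v_boot[, , b] <- sv$v[, seq_len(k), drop = FALSE] %*%
      (sv$d[seq_len(k)] * Q)                       # scaled saliences, rotated
    xs_b <- Xb %*% Vb
    load_boot[, , b] <- stats::cor(Y[idx, , drop = FALSE], xs_b)
  }

  vs_obs <- obs$v * rep(obs$singular_values, each = nv)
  boot_sd <- apply(v_boot, c(1, 2), stats::sd)
  bsr <- vs_obs / boot_sd
  bsr[!is.finite(bsr)] <- sign(vs_obs[!is.finite(bsr)]) * bsr_cap
  bsr <- clip_range(bsr, -bsr_cap, bsr_cap)

  loadings <- matrix(vapply(seq_len(k), function(i) {
    stats::cor(Y, obs$imaging_scores[, i])[, 1]
  }, numeric(nb)), nb, k)
  alpha <- (1 - conf) / 2
  ci_lo <- apply(load_boot, c(1, 2), stats::quantile, probs = alpha, na.rm = TRUE)
  ci_hi <- apply(load_boot, c(1, 2), stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  dimnames(bsr) <- dimnames(obs$v)
  rn <- colnames(Y)
  dimnames(loadings) <- dimnames(ci_lo) <- dimnames(ci_hi) <-
    list(rn, paste0("LV", seq_len(k)))

  list(bootstrap_ratios = bsr, boot_sd = boot_sd,
       bsr_significant = abs(bsr) > bsr_threshold,
       bsr_threshold = bsr_threshold,
       loadings = loadings,
       loading_ci_lower = ci_lo, loading_ci_upper = ci_hi,
       loading_significant = ci_lo > 0 | ci_hi < 0,
       n_redraws = n_redraws)
}

#' Correlation between imaging and behavioural composite scores
#'
#' Pearson r per LV between `X_z V` and `Y_z U`; invariant to a joint
#' sign flip of an LV's salience pair.
#'
#' @param result a `plsc_result`.
#' @return numeric vector, one r per LV.
#' @export
score_correlation <- function(result) {
  stopifnot(inherits(result, "plsc_result"))
  result$score_correlation
}

#' Full PLS correlation analysis of one seed network
#'
#' Decomposition, permutation test, and bootstrap inference in one call,
#' with permutation and bootstrap streams derived independently from one
#' root seed.
#'
#' @param X,Y the PLS blocks.
#' @param n_perm,n_boot resampling sizes.
#' @param seed root seed.
#' @param ... passed to [bootstrap_inference()].
#' @return list of class `plsc_analysis` combining the [plsc_fit()]
#'   result with `perm_p` and the bootstrap fields.
#' @export
plsc_run <- function(X, Y, n_perm = 1000, n_boot = 1000, seed = 1L, ...) {
  fit <- plsc_fit(X, Y)
  perm <- permutation_test(X, Y, n_perm = n_perm, seed = seed)
  boot <- bootstrap_inference(X, Y, n_boot = n_boot, seed = seed, ...)
  structure(c(fit, list(perm_p = perm$perm_p), boot),
            class = "plsc_analysis")
}
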