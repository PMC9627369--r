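# Shared fixtures and independent brute-force oracles.

# pooled-variance two-sample t statistic, closed form
oracle_two_sample_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Benjamini-Hochberg step-up by direct enumeration
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# PLS correlation decomposition oracle: entrywise correlation matrix and
# eigendecomposition of R'R / RR' (independent of the svd() path)
oracle_plsc <- function(X, Y) {
  R <- matrix(0, ncol(Y), ncol(X))
  for (i in seq_len(ncol(Y))) {
    for (j in seq_len(ncol(X))) R[i, j] <- cor(Y[, i], X[, j])
  }
  ev <- eigen(R %*% t(R), symmetric = TRUE)
  d <- sqrt(pmax(ev$values, 0))
  U <- ev$vectors
  # right vectors from the left ones; guard the zero singular values
  V <- sapply(seq_along(d), function(i) {
    if (d[i] > 1e-12) as.numeric(t(R) %*% U[, i]) / d[i] else rep(0, ncol(X))
  })
  list(d = d, U = U, V = V, R = R)
}

# direct-formula ComBat oracle for a covariate-free design: standardize,
# EB-update per batch by the same conditional equations, written
# independently in scalar loops
oracle_combat <- function(dat, batch, tol = 1e-8, maxit = 5000) {
  batch <- factor(batch)
  n <- ncol(dat); G <- nrow(dat)
  nb <- nlevels(batch)
  n_i <- as.numeric(table(batch))
  # per-feature OLS on batch indicators
  batch_means <- sapply(levels(batch), function(b) rowMeans(dat[, batch == b, drop = FALSE]))
  alpha <- as.numeric(batch_means %*% (n_i / n))
  resid <- dat
  for (b in seq_len(nb)) {
    sel <- batch == levels(batch)[b]
    resid[, sel] <- dat[, sel] - batch_means[, b]
  }
  sigma2 <- rowSums(resid^2) / n
  z <- (dat - alpha) / sqrt(sigma2)
  g_hat <- sapply(levels(batch), function(b) rowMeans(z[, batch == b, drop = FALSE]))
  d_hat <- sapply(levels(batch), function(b) apply(z[, batch == b, drop = FALSE], 1, var))
  out <- dat
  for (b in seq_len(nb)) {
    sel <- batch == levels(batch)[b]
    gbar <- mean(g_hat[, b]); t2 <- var(g_hat[, b])
    m <- mean(d_hat[, b]); s2 <- var(d_hat[, b])
    ap <- (2 * s2 + m^2) / s2
    bp <- (m * s2 + m^3) / s2
    g <- g_hat[, b]; d <- d_hat[, b]
    for (it in seq_len(maxit)) {
      g_old <- g; d_old <- d
      g <- (n_i[b] * t2 * g_hat[, b] + d * gbar) / (n_i[b] * t2 + d)
      ss <- rowSums((z[, sel, drop = FALSE] - g)^2)
      d <- (0.5 * ss + bp) / (n_i[b] / 2 + ap - 1)
      if (max(abs(g - g_old), abs(d - d_old)) < tol) break
    }
    out[, sel] <- (z[, sel, drop = FALSE] - g) / sqrt(d) * sqrt(sigma2) + alpha
  }
  out
}

# rank-1 coupled blocks: n subjects, informative + null voxels, one
# latent factor driving both blocks
planted_blocks <- function(n = 100, n_inf = 20, n_null = 30, n_beh = 4,
                           r_x = 0.7, r_y = 0.6, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  X <- cbind(
    sapply(seq_len(n_inf), function(i) r_x * f + sqrt(1 - r_x^2) * rnorm(n)),
    matrix(rnorm(n * n_null), n)
  )
  Y <- sapply(seq_len(n_beh), function(i) r_y * f + sqrt(1 - r_y^2) * rnorm(n))
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  colnames(Y) <- paste0("b", seq_len(n_beh))
  list(X = X, Y = Y, f = f, n_inf = n_inf)
}

# independent column z-scoring (base scale, denominator n - 1)
.zscore_test <- function(M) scale(M)

# small default-structure spec for fast end-to-end tests
tiny_spec <- function(n_pd = 30, n_hc = 30, t_len = 60, seed = 1, ...) {
  simulation_spec(n_pd = n_pd, n_hc = n_hc, t_len = t_len, seed = seed, ...)
}
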