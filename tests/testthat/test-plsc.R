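test_that("residualization produces exact OLS orthogonality", {
  set.seed(71)
  n <- 50
  age <- rnorm(n, 60, 8)
  nuis <- cbind(age = age, edu = rnorm(n, 12, 3))
  M <- cbind(y1 = 2 * age + rnorm(n, sd = 0.5), y2 = rnorm(n))
  R <- residualize(M, nuis)
  expect_lt(max(abs(crossprod(nuis, R))), 1e-8)
  expect_lt(max(abs(colSums(R))), 1e-8)          # intercept removed
  expect_lt(abs(cor(R[, "y1"], age)), 1e-8)

  # intercept-only: column centring
  expect_equal(residualize(M), scale(M, scale = FALSE), ignore_attr = TRUE)
  # column equal to a nuisance covariate: residual identically zero
  expect_lt(max(abs(residualize(cbind(age), nuis))), 1e-10)
  # collinear nuisance errors with the offending column named
  expect_error(residualize(M, cbind(age = age, age2 = 2 * age)),
               "collinear")
})

test_that("a noise-free rank-1 coupling yields a single perfect LV", {
  set.seed(73)
  # exactly uncorrelated voxels: orthogonalize the centred columns
  X <- qr.Q(qr(scale(matrix(rnorm(40 * 3), 40), scale = FALSE)))
  colnames(X) <- paste0("v", 1:3)
  Y <- cbind(b1 = X[, 2])
  fit <- plsc_fit(X, Y)
  expect_equal(fit$cov_explained[1], 1, tolerance = 1e-12)
  expect_equal(fit$score_correlation[1], 1, tolerance = 1e-10)
  expect_equal(abs(fit$v[2, 1]), 1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("independent blocks give uniformly small singular values", {
  set.seed(79)
  X <- matrix(rnorm(1000 * 5), 1000)
  Y <- matrix(rnorm(1000 * 3), 1000)
  fit <- plsc_fit(X, Y)
  expect_true(all(fit$singular_values < 0.15))
})

test_that("decomposition matches the eigendecomposition oracle on a fixed toy", {
  X <- matrix(c(1, 4, 2, 7,
                3, 0, 5, 1,
                2, 2, 2, 6), 4, 3)
  colnames(X) <- paste0("v", 1:3)
  Y <- matrix(c(2, 9, 1, 5,
                0, 3, 4, 8), 4, 2)
  colnames(Y) <- paste0("b", 1:2)
  fit <- plsc_fit(X, Y)
  orc <- oracle_plsc(X, Y)
  expect_equal(fit$singular_values, orc$d, tolerance = 1e-10)
  expect_equal(crossprod(.zscore_test(Y), .zscore_test(X)) / 3,
               orc$R, tolerance = 1e-10, ignore_attr = TRUE)
  for (i in 1:2) {   # vectors agree up to joint sign
    s <- sign(sum(fit$u[, i] * orc$U[, i]))
    expect_equal(fit$u[, i], s * orc$U[, i], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit$v[, i], s * orc$V[, i], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("covariance explained sums to one and is order-invariant", {
  set.seed(83)
  b <- planted_blocks(n = 60, n_inf = 8, n_null = 8, n_beh = 4, seed = 83)
  fit <- plsc_fit(b$X, b$Y)
  expect_equal(sum(fit$cov_explained), 1, tolerance = 1e-10)
  permX <- sample(ncol(b$X)); permY <- sample(ncol(b$Y))
  fit2 <- plsc_fit(b$X[, permX], b$Y[, permY])
  expect_equal(fit2$singular_values, fit$singular_values, tolerance = 1e-10)
  expect_equal(abs(fit2$v[, 1]), abs(fit$v[permX, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zero-variance columns are rejected with their names", {
  X <- matrix(rnorm(30), 10, 3); colnames(X) <- c("a", "bad", "c")
  X[, 2] <- 7
  Y <- matrix(rnorm(20), 10, 2)
  expect_error(plsc_fit(X, Y), "bad")
})

test_that("permutation p is exact for a perfect coupling and reproducible", {
  set.seed(89)
  X <- matrix(rnorm(30 * 2), 30)
  Y <- cbind(X[, 1])
  colnames(X) <- c("v1", "v2"); colnames(Y) <- "b1"
  p1 <- permutation_test(X, Y, n_perm = 199, seed = 4)
  expect_equal(p1$perm_p[1], 1 / 200)    # no permutation reaches s1 = 1
  p2 <- permutation_test(X, Y, n_perm = 199, seed = 4)
  expect_identical(p1$perm_p, p2$perm_p)
  p3 <- permutation_test(X, Y, n_perm = 199, seed = 5)
  expect_false(identical(p1$perm_singvals, p3$perm_singvals))
  expect_warning(permutation_test(X, Y, n_perm = 50, seed = 1), "coarse")
})

test_that("permutation p of LV-1 is uniform under independent null blocks", {
  set.seed(97)
  pvals <- replicate(200, {
    X <- matrix(rnorm(40 * 10), 40)
    Y <- matrix(rnorm(40 * 4), 40)
    permutation_test(X, Y, n_perm = 200,
                     seed = sample.int(1e6, 1))$perm_p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("bootstrap flags a noise-free informative voxel with capped BSR", {
  set.seed(101)
  X <- matrix(rnorm(40 * 3), 40)
  colnames(X) <- paste0("v", 1:3)
  Y <- cbind(b1 = X[, 2])
  boot <- bootstrap_inference(X, Y, n_boot = 100, seed = 6)
  expect_equal(abs(boot$bootstrap_ratios[2, 1]), 1e6, ignore_attr = TRUE)
  expect_true(boot$bsr_significant[2, 1])
  expect_true(boot$loading_significant[1, 1])
})

test_that("null-block bootstrap ratios rarely exceed the 3.3 threshold", {
  # blocks at the pipeline's shape: ~200 network voxels, 8 scores
  set.seed(103)
  rates <- replicate(40, {
    X <- matrix(rnorm(100 * 200), 100)
    Y <- matrix(rnorm(100 * 8), 100)
    b <- bootstrap_inference(X, Y, n_boot = 100,
                             seed = sample.int(1e6, 1))
    mean(abs(b$bootstrap_ratios[, 1]) > 3.3)
  })
  expect_lte(mean(rates), 0.01)
})

test_that("a planted behavioural loading is detected by its bootstrap CI", {
  hits <- sapply(1:30, function(i) {
    b <- planted_blocks(n = 150, n_inf = 10, n_null = 10, n_beh = 3,
                        r_x = 0.7, r_y = 0.6, seed = 300 + i)
    bi <- bootstrap_inference(b$X, b$Y, n_boot = 200, seed = i)
    bi$loading_significant[1, 1]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("score correlations behave under nulls and sign flips", {
  set.seed(107)
  X <- matrix(rnorm(1000 * 4), 1000)
  Y <- matrix(rnorm(1000 * 3), 1000)
  fit <- plsc_fit(X, Y)
  expect_true(all(abs(score_correlation(fit)) < 0.1))
  # joint sign flip leaves the score correlation unchanged
  r1 <- cor(fit$imaging_scores[, 1], fit$behavioral_scores[, 1])
  r2 <- cor(-fit$imaging_scores[, 1], -fit$behavioral_scores[, 1])
  expect_equal(r1, r2)
  expect_true(all(abs(score_correlation(fit)) <= 1))
})

test_that("LV-1 salience recovers the planted pattern", {
  b <- planted_blocks(n = 100, n_inf = 200, n_null = 800, n_beh = 4,
                      r_x = 0.6, r_y = 0.6, seed = 109)
  fit <- plsc_fit(b$X, b$Y)
  planted <- c(rep(1, b$n_inf), rep(0, 800)) / sqrt(b$n_inf)
  cosine <- abs(sum(fit$v[, 1] * planted)) /
    sqrt(sum(fit$v[, 1]^2) * sum(planted^2))
  expect_gt(cosine, 0.9)
})

test_that("voxel-score correlations rank-order with salience magnitudes", {
  # graded planted couplings so the ranking carries real signal
  set.seed(127)
  n <- 150
  f <- rnorm(n)
  rx <- seq(0.1, 0.8, length.out = 40)
  X <- sapply(rx, function(r) r * f + sqrt(1 - r^2) * rnorm(n))
  colnames(X) <- paste0("v", seq_along(rx))
  Y <- sapply(1:4, function(i) 0.6 * f + 0.8 * rnorm(n))
  colnames(Y) <- paste0("b", 1:4)
  fit <- plsc_fit(X, Y)
  vox_cor <- abs(cor(X, fit$imaging_scores[, 1]))
  expect_gt(cor(vox_cor, abs(fit$v[, 1]), method = "spearman"), 0.95)
})

test_that("residualized rerun recovers opposite-signed planted loadings", {
  # extended first pass, then nuisance removed from both blocks: the two
  # oppositely-planted behaviours load LV-1 with opposite signs
  set.seed(113)
  n <- 120
  f <- rnorm(n)                      # latent severity
  age <- rnorm(n, 60, 8)             # nuisance contaminating both blocks
  X <- sapply(1:40, function(i) 0.6 * f + 0.01 * age + rnorm(n))
  colnames(X) <- paste0("v", 1:40)
  stai <- 0.7 * f + 0.02 * age + rnorm(n, sd = 0.7)
  moca <- -0.5 * f - 0.01 * age + rnorm(n, sd = 0.8)
  Y <- cbind(STAI = stai, MoCA = moca)
  first <- plsc_fit(cbind(X), cbind(Y, age = age))
  expect_gt(first$cov_explained[1], 0.5)
  Xr <- residualize(X, cbind(age))
  Yr <- residualize(Y, cbind(age))
  perm <- permutation_test(Xr, Yr, n_perm = 500, seed = 9)
  expect_lt(perm$perm_p[1], 0.05)
  fit <- plsc_fit(Xr, Yr)
  expect_lt(fit$u["STAI", 1] * fit$u["MoCA", 1], 0)
})
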