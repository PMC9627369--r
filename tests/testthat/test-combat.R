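# Two-site feature matrix with known location/scale batch structure.
# Features are simulated at the scale the module harmonizes in the
# pipeline: Fisher-z maps, whose between-subject SD is ~0.1, against
# which the planted site offset of 1.0 is large.
sim_batch_data <- function(n_per_site = 200, n_feat = 100, gamma = c(0, 1),
                           delta = c(1, 1), group_effect = 0, seed = 1,
                           sigma = 0.15) {
  set.seed(seed)
  n <- 2 * n_per_site
  batch <- rep(c("a", "b"), each = n_per_site)
  group <- rep(rep(0:1, length.out = n_per_site), 2)
  base <- matrix(rnorm(n_feat * n, sd = sigma), n_feat, n)
  dat <- base + group_effect * matrix(group, n_feat, n, byrow = TRUE)
  for (b in 1:2) {
    sel <- batch == c("a", "b")[b]
    dat[, sel] <- dat[, sel] * delta[b] + gamma[b]
  }
  list(dat = dat, batch = batch, group = group)
}

test_that("harmonization removes a planted additive site offset", {
  d <- sim_batch_data(gamma = c(0, 1), seed = 11)
  h <- suppressMessages(harmonize(d$dat, d$batch))
  delta_means <- rowMeans(h$data[, d$batch == "b"]) -
    rowMeans(h$data[, d$batch == "a"])
  expect_lt(mean(abs(delta_means)), 0.05)
})

test_that("harmonization equalizes a planted site scale factor", {
  d <- sim_batch_data(delta = c(1, 2), seed = 12)
  h <- suppressMessages(harmonize(d$dat, d$batch))
  ratio <- apply(h$data[, d$batch == "b"], 1, var) /
    apply(h$data[, d$batch == "a"], 1, var)
  expect_gt(mean(ratio), 0.9)
  expect_lt(mean(ratio), 1.1)
})

test_that("a group effect in the design survives harmonization", {
  # pure site offset: the planted 0.3 group difference is recovered
  d <- sim_batch_data(gamma = c(0, 1), delta = c(1, 1),
                      group_effect = 0.3, seed = 13)
  h <- suppressMessages(harmonize(d$dat, d$batch,
                                  design = cbind(group = d$group)))
  eff <- rowMeans(h$data[, d$group == 1]) - rowMeans(h$data[, d$group == 0])
  expect_lt(mean(abs(eff - 0.3)), 0.05)

  # with a site scale factor the observed pooled difference changes by
  # less than 0.05 from its pre-harmonization value (not absorbed)
  d2 <- sim_batch_data(gamma = c(0, 1), delta = c(1, 1.5),
                       group_effect = 0.3, seed = 131)
  pre <- rowMeans(d2$dat[, d2$group == 1]) - rowMeans(d2$dat[, d2$group == 0])
  h2 <- suppressMessages(harmonize(d2$dat, d2$batch,
                                   design = cbind(group = d2$group)))
  post <- rowMeans(h2$data[, d2$group == 1]) - rowMeans(h2$data[, d2$group == 0])
  expect_lt(mean(abs(post - pre)), 0.05)
})

test_that("identity site effects leave the data essentially unchanged", {
  # gamma* ~ 0, delta* ~ 1: adjustment is within EB-shrinkage noise
  d <- sim_batch_data(n_per_site = 300, gamma = c(0, 0), delta = c(1, 1),
                      seed = 14)
  h <- suppressMessages(harmonize(d$dat, d$batch))
  expect_lt(sqrt(mean((h$data - d$dat)^2)), 0.1 * 0.15)
})

test_that("single-site input bypasses harmonization untouched", {
  set.seed(15)
  dat <- matrix(rnorm(200), 20)
  h <- suppressMessages(harmonize(dat, rep("x", 10)))
  expect_identical(h$data, dat)
  expect_null(h$model)
  expect_error(fit_combat(dat, rep("x", 10)), "one site")
})

test_that("fit/apply matches an independently coded direct-formula oracle", {
  # covariate-free toy small enough for the scalar-loop oracle
  set.seed(16)
  dat <- matrix(rnorm(8 * 40, mean = 2), 8, 40)
  batch <- rep(c("a", "b"), each = 20)
  dat[, batch == "b"] <- dat[, batch == "b"] * 1.4 + 0.7
  model <- fit_combat(dat, batch, tol = 1e-8, maxit = 5000)
  ours <- apply_combat(model, dat)
  oracle <- oracle_combat(dat, batch)
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("harmonized output matches the reference sva implementation", {
  skip_if_not_installed("sva")
  d <- sim_batch_data(n_per_site = 40, n_feat = 60, gamma = c(0, 0.8),
                      delta = c(1, 1.6), group_effect = 0.4, seed = 17)
  mod <- model.matrix(~ d$group)
  ref <- suppressMessages(sva::ComBat(d$dat, batch = d$batch, mod = mod))
  h <- suppressMessages(harmonize(d$dat, d$batch,
                                  design = cbind(group = d$group),
                                  tol = 1e-6, maxit = 2000))
  expect_equal(unname(h$data), unname(ref), tolerance = 1e-4)
})

test_that("harmonizing twice is nearly idempotent on null data", {
  # null z-map-scale simulation at the pipeline's 3:1 site split
  set.seed(18)
  n1 <- 162; n2 <- 54
  batch <- rep(c("a", "b"), c(n1, n2))
  dat <- matrix(rnorm(300 * (n1 + n2), sd = 0.07), 300)
  h1 <- suppressMessages(harmonize(dat, batch))
  h2 <- suppressMessages(harmonize(h1$data, batch))
  expect_lt(sqrt(mean((h2$data - h1$data)^2)), 1e-3)
})

test_that("EB location estimates shrink toward the prior as sites get small", {
  # fixed features; per-site n grows: gamma* approaches the raw estimate
  shrink <- sapply(c(6, 20, 100), function(ns) {
    d <- sim_batch_data(n_per_site = ns, n_feat = 50, gamma = c(0, 0.5),
                        seed = 19)
    m <- fit_combat(d$dat, d$batch)
    mean(abs(m$gamma_star - m$gamma_hat))
  })
  expect_true(all(diff(shrink) < 0))
})

test_that("gamma* lies between the raw estimate and the prior mean", {
  d <- sim_batch_data(n_per_site = 30, n_feat = 60, gamma = c(0, 0.6), seed = 20)
  m <- fit_combat(d$dat, d$batch)
  gbar <- matrix(m$prior_params$gamma_bar, nrow(m$gamma_hat), 2, byrow = TRUE)
  expect_true(all(abs(m$gamma_star - gbar) <= abs(m$gamma_hat - gbar) + 1e-12))
  expect_true(all(m$delta_star > 0))
})

test_that("zero-variance and missing features are dropped and passed through", {
  d <- sim_batch_data(n_per_site = 20, n_feat = 30, seed = 21)
  d$dat[3, ] <- 5                  # constant feature
  d$dat[7, 2] <- NA                # missing value
  expect_message(model <- fit_combat(d$dat, d$batch), "excluding 2 feature")
  expect_warning(out <- apply_combat(model, d$dat), "passed through")
  expect_equal(out[3, ], d$dat[3, ])
  expect_equal(out[7, ], d$dat[7, ])
  expect_false(any(is.na(out[-7, ])))
})

test_that("degenerate designs error clearly", {
  d <- sim_batch_data(n_per_site = 20, n_feat = 10, seed = 22)
  site_dummy <- as.numeric(d$batch == "b")
  expect_error(fit_combat(d$dat, d$batch, design = cbind(site_dummy)),
               "rank-deficient")
  expect_error(fit_combat(d$dat, c(rep("a", 39), "b")), "at least 2 subjects")
})

test_that("harmonization preserves type-I error of the downstream contrast", {
  # no site effect planted: rejection rate of the group test stays nominal
  set.seed(23)
  n <- 60
  cohort <- data.frame(group = rep(c("PD", "HC"), each = n / 2),
                       site = rep(c("a", "b"), n / 2),
                       stringsAsFactors = FALSE)
  z <- matrix(rnorm(500 * n), 500, n)
  h <- suppressMessages(harmonize(z, cohort$site,
                                  design = cbind(group = as.numeric(cohort$group == "PD"))))
  gr <- suppressMessages(voxelwise_group_contrast(h$data, cohort,
                                                  covariates = character(0)))
  rate <- mean(gr$p < 0.05)
  ci <- qbinom(c(0.005, 0.995), 500, 0.05) / 500
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
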