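# Empirical-Bayes location/scale harmonization of multi-site feature
# matrices (parametric ComBat model), with an explicit fit/apply split.

#' Fit the empirical-Bayes site-harmonization model
#'
#' Models each feature (voxel) `g` of subject `j` in site `i` as
#' `y_ijg = alpha_g + X_j beta_g + gamma_ig + delta_ig eps_ijg`,
#' where `X` holds covariates whose effects must be preserved. Features
#' are standardized by the covariate fit and pooled residual SD; per-site
#' location (`gamma`) and scale (`delta^2`) estimates are shrunk toward
#' normal / inverse-gamma priors whose hyperparameters are estimated by
#' method of moments, using iterative conditional empirical-Bayes updates
#' until the sup-norm change falls below `tol`.
#'
#' Features with zero variance, or with a missing value in any subject,
#' are excluded from the fit (reported via a message) and passed through
#' unharmonized by [apply_combat()].
#'
#' @param data features x subjects matrix.
#' @param batch site label per subject (>= 2 sites, >= 2 subjects each).
#' @param design optional subjects x covariates numeric matrix of effects
#'   to preserve (no intercept; one is added internally).
#' @param tol convergence tolerance for the EB updates.
#' @param maxit maximum EB iterations per site.
#' @return object of class `combat_model`.
#' @export
fit_combat <- function(data, batch, design = NULL, tol = 1e-4, maxit = 200) {
  data <- as.matrix(data)
  batch <- factor(batch)
  n <- ncol(data)
  stopifnot(length(batch) == n)
  if (nlevels(batch) < 2) {
    stop("only one site present: skip harmonization (nothing to remove)")
  }
  n_i <- table(batch)
  if (any(n_i < 2)) stop("each site must have at least 2 subjects")

  rmu <- rowMeans(data)
  rvar <- rowSums((data - rmu)^2) / (n - 1)
  keep <- which(rowSums(is.na(data)) == 0 & !is.na(rvar) & rvar > 0)
  dropped <- setdiff(seq_len(nrow(data)), keep)
  if (length(dropped)) {
    message("fit_combat: excluding ", length(dropped),
            " feature(s) with missing values or zero variance")
  }
  if (!length(keep)) stop("no usable features")
  dat <- data[keep, , drop = FALSE]

  batchmod <- stats::model.matrix(~ -1 + batch)
  if (!is.null(design)) {
    design <- as.matrix(design)
    stopifnot(nrow(design) == n)
  }
  X <- cbind(batchmod, design)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: covariates are collinear with each other or with site")
  }
  nb <- nlevels(batch)

  # covariate + batch OLS fit, feature-wise
  B_hat <- solve(crossprod(X), t(X) %*% t(dat))         # p x G
  grand_mean <- as.numeric(crossprod(n_i / n, B_hat[seq_len(nb), , drop = FALSE]))
  resid <- dat - t(X %*% B_hat)
  var_pooled <- rowMeans(resid^2)                        # divide by n, as in EB ComBat

  stand_mean <- matrix(grand_mean, length(keep), n)
  if (!is.null(design)) {
    stand_mean <- stand_mean +
      t(design %*% B_hat[-seq_len(nb), , drop = FALSE])
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(batchmod), t(batchmod) %*% t(s_data))) # G x nb
  delta_hat <- vapply(levels(batch), function(b) {
    sb <- s_data[, batch == b, drop = FALSE]
    rowSums((sb - rowMeans(sb))^2) / (ncol(sb) - 1)
  }, numeric(length(keep)))                                             # G x nb

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(nb)
  for (i in seq_len(nb)) {
    sd_i <- s_data[, batch == levels(batch)[i], drop = FALSE]
    ni <- ncol(sd_i)
    g_new <- gamma_hat[, i]
    d_new <- delta_hat[, i]
    for (it in seq_len(maxit)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (ni * t2[i] * gamma_hat[, i] + d_old * gamma_bar[i]) /
        (ni * t2[i] + d_old)
      sum2 <- rowSums((sd_i - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol) break
    }
    if (it == maxit) warning("EB updates for site ", levels(batch)[i],
                             " did not converge in ", maxit, " iterations")
    iters[i] <- it
    gamma_star[, i] <- g_new
    delta_star[, i] <- d_new
  }

  structure(
    list(batch_levels = levels(batch), batch = batch, n_per_site = as.integer(n_i),
         keep = keep, n_features = nrow(data), dropped = dropped,
         B_hat = B_hat, n_batch = nb, design = design,
         grand_mean = grand_mean, var_pooled = var_pooled,
         stand_mean = stand_mean,
         gamma_hat = gamma_hat, delta_hat = delta_hat,
         gamma_star = gamma_star, delta_star = delta_star,
         prior_params = list(gamma_bar = gamma_bar, t2 = t2,
                             a_prior = a_prior, b_prior = b_prior),
         iterations = iters),
    class = "combat_model"
  )
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat model:", x$n_batch, "sites (",
      paste(x$n_per_site, collapse = "/"), "subjects ),",
      length(x$keep), "features fitted,", length(x$dropped), "passed through\n")
  invisible(x)
}

#' Apply a fitted harmonization model
#'
#' Adjusted values are
#' `y* = sqrt(var_pooled / delta*) * (z - gamma*) + alpha + X beta`,
#' where `z` is the standardized data. By default the model is applied to
#' the data it was fitted on; a new matrix over the same subjects may be
#' supplied. Features that were excluded from the fit are passed through
#' unchanged with a warning; missing values propagate.
#'
#' @param model a `combat_model`.
#' @param data features x subjects matrix (defaults to refitting input is
#'   not stored, so this is required).
#' @param batch site labels (defaults to the fit labels).
#' @return harmonized matrix of the same shape as `data`.
#' @export
apply_combat <- function(model, data, batch = model$batch) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == model$n_features)
  batch <- factor(batch, levels = model$batch_levels)
  if (anyNA(batch)) stop("subject with site not present in the fitted model")
  stopifnot(length(batch) == ncol(data))

  out <- data
  if (length(model$dropped)) {
    warning(length(model$dropped),
            " feature(s) not in the fit are passed through unharmonized")
  }
  dat <- data[model$keep, , drop = FALSE]
  s_data <- (dat - model$stand_mean) / sqrt(model$var_pooled)
  ib <- as.integer(batch)
  adj <- (s_data - model$gamma_star[, ib, drop = FALSE]) /
    sqrt(model$delta_star[, ib, drop = FALSE])
  out[model$keep, ] <- adj * sqrt(model$var_pooled) + model$stand_mean
  out
}

#' Harmonize a feature matrix across sites in one call
#'
#' Fits and applies the empirical-Bayes model. With a single site the
#' data are returned unchanged with a message (bypass mode). Features
#' containing missing values are passed through unharmonized.
#'
#' @inheritParams fit_combat
#' @return list with the harmonized `data` and the `model` (`NULL` in
#'   bypass mode).
#' @export
harmonize <- function(data, batch, design = NULL, tol = 1e-4, maxit = 200) {
  if (length(unique(batch)) < 2) {
    message("harmonize: single site, returning data unchanged")
    return(list(data = as.matrix(data), model = NULL))
  }
  model <- fit_combat(data, batch, design, tol, maxit)
  list(data = suppressWarnings(apply_combat(model, data)), model = model)
}
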