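# Voxelwise group inference: OLS contrasts, BH-FDR, cluster-extent
# filtering, and the ROI-volume ANCOVA.

#' Voxelwise group contrast with nuisance covariates
#'
#' Fits, at every voxel, ordinary least squares of the Fisher-z value on
#' `[intercept, group, covariates]` and returns the t statistic and
#' two-sided p value for the group term (contrast PD - HC). Character or
#' factor covariates (e.g. sex) are coded 0/1. Voxels missing in any
#' subject are excluded and their count reported.
#'
#' @param z voxels x subjects matrix, columns aligned with `cohort` rows.
#' @param cohort cohort table containing `group` and the covariates.
#' @param covariates character vector of cohort column names.
#' @param seed_name label carried into the result.
#' @return object of class `glm_result` with per-voxel `t`, `p`, residual
#'   `df`, and `n_missing`.
#' @export
voxelwise_group_contrast <- function(z, cohort,
                                     covariates = c("sex", "age", "education", "mean_fd"),
                                     seed_name = "seed") {
  stopifnot(ncol(z) == nrow(cohort))
  g <- as.numeric(cohort$group == "PD")
  if (length(unique(g)) < 2 || min(table(cohort$group)) < 2) {
    stop("need at least 2 subjects per group")
  }
  X <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    col <- cohort[[cv]]
    if (is.null(col)) stop("covariate '", cv, "' not in cohort table")
    if (is.character(col) || is.factor(col)) {
      col <- as.numeric(factor(col)) - 1
    }
    X <- cbind(X, col)
  }
  colnames(X) <- c("intercept", "group", covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  n <- nrow(X)
  df <- n - ncol(X)

  ok <- rowSums(is.na(z)) == 0
  n_missing <- sum(!ok)
  if (n_missing > 0) {
    message("voxelwise_group_contrast: excluding ", n_missing,
            " voxel(s) with missing values")
  }
  tval <- pval <- rep(NA_real_, nrow(z))
  if (any(ok)) {
    zt <- t(z[ok, , drop = FALSE])                    # subjects x voxels
    B <- qr.coef(qx, zt)                              # p x voxels
    res <- zt - X %*% B
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    tv <- B[2, ] / se
    tval[ok] <- tv
    pval[ok] <- 2 * stats::pt(-abs(tv), df)
  }
  structure(list(seed_name = seed_name, t = tval, p = pval, df = df,
                 contrast = "PD-HC", n_missing = n_missing,
                 design_columns = colnames(X)),
            class = "glm_result")
}

#' Benjamini-Hochberg FDR correction over a voxel map
#'
#' Step-up adjustment via [stats::p.adjust()] over all non-missing voxels
#' of one seed's map; the rejection set is `p_adj <= q`.
#'
#' @param p raw two-sided p values (`NA` = missing voxel).
#' @param q FDR level.
#' @return list with logical `reject`, numeric `p_adj`, and `q`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0 || all(is.na(p))) stop("empty p-value input")
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p values must lie in (0, 1]")
  p_adj <- rep(NA_real_, length(p))
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  reject <- !is.na(p_adj) & p_adj <= q
  list(reject = reject, p_adj = p_adj, q = q)
}

# neighbourhood offsets for 6/18/26-connectivity
.neighbour_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 18, 26))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' Breadth-first labelling under a 6-, 18-, or 26-neighbourhood.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18, or 26 (default).
#' @return integer 3D array of cluster ids (0 = background).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  off <- .neighbour_offsets(connectivity)
  labels <- array(0L, dims)
  next_id <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    labels[start] <- next_id
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- voxel_coords(cur, dims)
      nb <- sweep(off, 2, as.numeric(co), `+`)
      inb <- nb[nb[, 1] >= 1 & nb[, 1] <= dims[1] &
                  nb[, 2] >= 1 & nb[, 2] <= dims[2] &
                  nb[, 3] >= 1 & nb[, 3] <= dims[3], , drop = FALSE]
      lin <- inb[, 1] + (inb[, 2] - 1L) * dims[1] +
        (inb[, 3] - 1L) * dims[1] * dims[2]
      new <- lin[mask[lin] & labels[lin] == 0L]
      labels[new] <- next_id
      queue <- c(queue, new)
    }
  }
  labels
}

#' Cluster-extent filtering of a significance mask
#'
#' Labels the connected components of the rejection mask and removes every
#' component smaller than `k_min` voxels.
#'
#' @param mask logical 3D array (or in-mask logical vector plus
#'   `mask_idx`/`grid_dims`).
#' @param k_min minimal surviving cluster size in voxels (default 20).
#' @param connectivity 6, 18, or 26 (default).
#' @param seed_name label carried into the result.
#' @param q FDR level recorded alongside.
#' @param mask_idx,grid_dims needed when `mask` is an in-mask vector.
#' @return object of class `significance_mask` with the filtered logical
#'   `mask`, integer `cluster_labels`, a `sizes` table of surviving
#'   clusters, `k_min`, and `q`.
#' @export
cluster_extent_filter <- function(mask, k_min = 20, connectivity = 26,
                                  seed_name = "seed", q = 0.05,
                                  mask_idx = NULL, grid_dims = NULL) {
  if (is.null(dim(mask))) {
    stopifnot(!is.null(mask_idx), !is.null(grid_dims))
    m3 <- array(FALSE, grid_dims)
    m3[mask_idx[mask]] <- TRUE
    mask <- m3
  }
  stopifnot(k_min >= 1)
  labels <- label_clusters(mask, connectivity)
  sizes <- tabulate(labels[labels > 0])
  keep_ids <- which(sizes >= k_min)
  out_mask <- array(labels %in% keep_ids, dim(mask))
  out_labels <- labels
  out_labels[!out_mask] <- 0L
  # relabel surviving clusters 1..K by decreasing size
  if (length(keep_ids)) {
    ord <- keep_ids[order(sizes[keep_ids], decreasing = TRUE)]
    remap <- integer(max(labels))
    remap[ord] <- seq_along(ord)
    out_labels[out_mask] <- remap[labels[out_mask]]
    sizes_out <- sizes[ord]
  } else {
    sizes_out <- integer(0)
  }
  structure(list(seed_name = seed_name, mask = out_mask,
                 cluster_labels = out_labels, sizes = sizes_out,
                 q = q, k_min = k_min, connectivity = connectivity),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat("Significance mask [", x$seed_name, "]: ", sum(x$mask), " voxels in ",
      length(x$sizes), " cluster(s) (k_min = ", x$k_min, ")\n", sep = "")
  invisible(x)
}

#' Tabulate surviving clusters
#'
#' One row per cluster: label, size, peak |t|, and the peak voxel's
#' 1-based (x, y, z) indices.
#'
#' @param sig a `significance_mask`.
#' @param glm_result the matching `glm_result` (same seed).
#' @param mask_idx in-mask linear indices aligning `glm_result$t` with
#'   the grid.
#' @return data.frame with columns label, size, peak_t, peak_x/y/z.
#' @export
cluster_table <- function(sig, glm_result, mask_idx) {
  dims <- dim(sig$mask)
  t_grid <- array(NA_real_, dims)
  t_grid[mask_idx] <- glm_result$t
  labs <- sort(unique(sig$cluster_labels[sig$cluster_labels > 0]))
  rows <- lapply(labs, function(l) {
    vox <- which(sig$cluster_labels == l)
    peak <- vox[which.max(abs(t_grid[vox]))]
    co <- voxel_coords(peak, dims)
    data.frame(label = l, size = length(vox), peak_t = t_grid[peak],
               peak_x = co[1], peak_y = co[2], peak_z = co[3])
  })
  if (!length(rows)) {
    return(data.frame(label = integer(0), size = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0)))
  }
  do.call(rbind, rows)
}

#' ANCOVA on an ROI volume
#'
#' Partial F-test for the group factor in
#' `volume ~ group + age + sex + education` (nested-model comparison).
#' With an empty covariate list this reduces exactly to the one-way
#' ANOVA F.
#'
#' @param cohort cohort table.
#' @param roi volume column name (e.g. `"vol_core_L"`).
#' @param covariates cohort column names adjusted for.
#' @return list with `F`, `p`, `df`, and the fitted model.
#' @export
ancova_volumes <- function(cohort, roi,
                           covariates = c("age", "sex", "education")) {
  if (is.null(cohort[[roi]])) stop("volume column '", roi, "' not in cohort table")
  if (anyNA(cohort[[roi]])) stop("missing values in volume column '", roi, "'")
  dat <- data.frame(vol = cohort[[roi]], group = factor(cohort$group))
  for (cv in covariates) dat[[cv]] <- cohort[[cv]]
  rhs <- paste(c("group", covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("vol ~", rhs)), data = dat)
  red <- stats::lm(
    stats::as.formula(paste("vol ~", paste(c("1", covariates), collapse = " + "))),
    data = dat)
  an <- stats::anova(red, full)
  list(F = an$F[2], p = an$`Pr(>F)`[2], df = c(an$Df[2], an$Res.Df[2]),
       model = full)
}
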