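# Seed time-course extraction, voxelwise correlation, Fisher r-to-z.

#' Probability-weighted ROI reference time course
#'
#' Returns the weighted mean `sum_v p_v x_v(t) / sum_v p_v` over the ROI's
#' support. With `binarize = TRUE` the probabilities are thresholded at
#' 0.5 and all surviving voxels weighted equally (sensitivity mode).
#'
#' @param bold a `bold_series`.
#' @param roi 3D probability array on the BOLD grid, or a probability
#'   vector over the in-mask voxels.
#' @param binarize average a 0.5-thresholded mask instead of weighting.
#' @return numeric time series of length T.
#' @export
extract_roi_timecourse <- function(bold, roi, binarize = FALSE) {
  p <- if (length(dim(roi)) == 3) roi[bold$mask_idx] else roi
  stopifnot(length(p) == nrow(bold$data))
  if (binarize) p <- as.numeric(p > 0.5)
  if (!any(p > 0)) stop("ROI has no voxel with probability > 0")
  tot <- sum(p)
  if (tot <= 0) stop("ROI has zero total probability")
  as.numeric(crossprod(bold$data, p)) / tot
}

#' Voxelwise Pearson correlation with a reference time course
#'
#' Correlates every in-mask voxel's series with the seed reference.
#' Zero-variance voxels yield `NA` (missing marker, never zero) with a
#' warning reporting their count; a constant reference is an error.
#'
#' @param bold a `bold_series`.
#' @param reference numeric time series of length T.
#' @return numeric vector of r in `[-1, 1]` over the in-mask voxels.
#' @export
voxelwise_fc <- function(bold, reference) {
  x <- bold$data
  stopifnot(length(reference) == ncol(x), ncol(x) >= 3)
  refc <- reference - mean(reference)
  ref_ss <- sum(refc^2)
  if (ref_ss <= 0) stop("reference time course is constant")
  xc <- x - rowMeans(x)
  ss <- rowSums(xc^2)
  r <- as.numeric(xc %*% refc) / sqrt(ss * ref_ss)
  bad <- ss <= 0
  if (any(bad)) {
    r[bad] <- NA_real_
    warning(sum(bad), " zero-variance voxel(s) set to missing")
  }
  clip_range(r, -1, 1)
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Correlations with
#' `|r| >= 1 - 1e-7` are clipped to `1 - 1e-7` before the transform, with
#' a message reporting how many values were clipped. Missing values pass
#' through; non-finite non-missing input is an error.
#'
#' @param r numeric vector (or matrix) of correlations in `[-1, 1]`.
#' @return Fisher-z values of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(is.nan(r) | is.infinite(r))) stop("non-finite correlation input")
  ok <- !is.na(r)
  if (any(abs(r[ok]) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  lim <- 1 - 1e-7
  n_clip <- sum(abs(r[ok]) > lim)
  if (n_clip > 0) message("fisher_z: clipped ", n_clip, " value(s) with |r| >= 1 - 1e-7")
  z <- atanh(clip_range(r, -lim, lim))
  z
}

#' Construct a per-subject, per-seed connectivity map
#'
#' @param subject_id subject identifier.
#' @param seed_name seed ROI name.
#' @param values Fisher-z values over the in-mask voxels (`NA` = missing).
#' @param mask_idx in-mask linear voxel indices.
#' @param grid_dims 3D grid dimensions.
#' @return object of class `fc_map`.
#' @export
fc_map <- function(subject_id, seed_name, values, mask_idx, grid_dims) {
  stopifnot(length(values) == length(mask_idx))
  structure(list(subject_id = subject_id, seed_name = seed_name,
                 values = values, mask_idx = mask_idx,
                 grid_dims = grid_dims),
            class = "fc_map")
}

#' Compute one subject's seed connectivity map end to end
#'
#' Reference extraction, voxelwise correlation, and Fisher z in one call.
#'
#' @inheritParams extract_roi_timecourse
#' @param seed_name name of the seed ROI in the atlas.
#' @param atlas a `prob_atlas`.
#' @return an `fc_map`.
#' @export
seed_fc_map <- function(bold, atlas, seed_name, binarize = FALSE) {
  ref <- extract_roi_timecourse(bold, atlas$rois[[seed_name]], binarize)
  r <- voxelwise_fc(bold, ref)
  fc_map(bold$subject_id, seed_name, fisher_z(r), bold$mask_idx,
         bold$grid_dims)
}

#' Connectivity maps for every seed of an atlas in one pass
#'
#' Equivalent to calling [seed_fc_map()] per seed, but the voxel time
#' series are centred once and all references correlated in a single
#' matrix product.
#'
#' @param bold a `bold_series`.
#' @param atlas a `prob_atlas`.
#' @param binarize passed to [extract_roi_timecourse()].
#' @return matrix of Fisher-z values, in-mask voxels x seeds.
#' @export
fc_all_seeds <- function(bold, atlas, binarize = FALSE) {
  refs <- vapply(atlas$rois, function(p) {
    extract_roi_timecourse(bold, p, binarize)
  }, numeric(ncol(bold$data)))
  refc <- refs - rep(colMeans(refs), each = nrow(refs))
  ref_ss <- colSums(refc^2)
  if (any(ref_ss <= 0)) stop("constant reference time course")
  xc <- bold$data - rowMeans(bold$data)
  ss <- rowSums(xc^2)
  r <- (xc %*% refc) / outer(sqrt(ss), sqrt(ref_ss))
  bad <- ss <= 0
  if (any(bad)) {
    r[bad, ] <- NA_real_
    warning(sum(bad), " zero-variance voxel(s) set to missing")
  }
  suppressMessages(fisher_z(clip_range(r, -1, 1)))
}

#' Stack per-subject connectivity maps into a voxels x subjects matrix
#'
#' @param maps list of `fc_map` objects sharing one seed and grid.
#' @return matrix with subject ids as column names and a `mask_idx`
#'   attribute.
#' @export
stack_fc_maps <- function(maps) {
  stopifnot(length(maps) > 0)
  midx <- maps[[1]]$mask_idx
  z <- vapply(maps, function(m) {
    stopifnot(identical(m$mask_idx, midx))
    m$values
  }, numeric(length(midx)))
  colnames(z) <- vapply(maps, `[[`, "", "subject_id")
  attr(z, "mask_idx") <- midx
  attr(z, "grid_dims") <- maps[[1]]$grid_dims
  z
}

#' Embed an in-mask value vector as a 3D array
#'
#' Out-of-mask voxels are `NA`, never zero-filled.
#' @param values vector over in-mask voxels.
#' @param mask_idx in-mask linear indices.
#' @param grid_dims grid dimensions.
#' @return numeric 3D array.
#' @export
embed_map <- function(values, mask_idx, grid_dims) {
  arr <- array(NA_real_, grid_dims)
  arr[mask_idx] <- values
  arr
}
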