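# Probabilistic seed atlas: construction, validation, synthetic generation.

SEED_NAMES <- c("core_L", "shell_L", "core_R", "shell_R")

#' Construct a probabilistic atlas object
#'
#' An atlas bundles a set of named seed probability maps with the brain mask
#' that defines the analysis domain. Probability maps are full 3D arrays in
#' `[0, 1]`; the mask is a logical array on the same grid.
#'
#' @param rois named list of 3D probability arrays.
#' @param brain_mask logical 3D array.
#' @param voxel_size numeric length-3, mm per axis.
#' @return An object of class `prob_atlas`.
#' @export
prob_atlas <- function(rois, brain_mask, voxel_size = c(2, 2, 2)) {
  dims <- dim(brain_mask)
  stopifnot(length(dims) == 3, is.logical(brain_mask))
  for (nm in names(rois)) {
    p <- rois[[nm]]
    if (!identical(dim(p), dims)) {
      stop("ROI '", nm, "' is not on the brain-mask grid")
    }
    if (any(p < 0 | p > 1)) stop("ROI '", nm, "' has probabilities outside [0, 1]")
    if (any(p > 0 & !brain_mask)) {
      stop("ROI '", nm, "' has support outside the brain mask")
    }
  }
  structure(
    list(grid_dims = dims, voxel_size = as.numeric(voxel_size),
         rois = rois, brain_mask = brain_mask),
    class = "prob_atlas"
  )
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat("Probabilistic atlas:", paste(x$grid_dims, collapse = "x"),
      "grid,", sum(x$brain_mask), "mask voxels\n")
  for (nm in names(x$rois)) {
    cat(sprintf("  %-8s %4d voxels with p > 0.5\n", nm, sum(x$rois[[nm]] > 0.5)))
  }
  invisible(x)
}

#' Centroid (probability-weighted, voxel units) of each ROI
#' @param atlas a `prob_atlas`.
#' @return matrix, one row per ROI, columns x/y/z.
#' @export
atlas_centroids <- function(atlas) {
  out <- t(vapply(atlas$rois, function(p) {
    idx <- which(p > 0)
    w <- p[idx]
    colSums(voxel_coords(idx, atlas$grid_dims) * w) / sum(w)
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Validate atlas invariants
#'
#' Checks probability range, mask containment, left/right centroid ordering
#' (left-labelled ROIs must sit at strictly smaller x-index than
#' right-labelled ones), and that each ROI has at least `min_core` voxels
#' above probability 0.5.
#'
#' @param atlas a `prob_atlas`.
#' @param min_core minimum high-probability voxel count per ROI.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_atlas <- function(atlas, min_core = 10) {
  for (nm in names(atlas$rois)) {
    if (sum(atlas$rois[[nm]] > 0.5) < min_core) {
      stop("ROI '", nm, "' has fewer than ", min_core, " voxels with p > 0.5")
    }
  }
  cen <- atlas_centroids(atlas)
  left <- grepl("_L$", rownames(cen))
  right <- grepl("_R$", rownames(cen))
  if (any(left) && any(right) && max(cen[left, "x"]) >= min(cen[right, "x"])) {
    stop("left-labelled ROI centroids must have smaller x-index than right-labelled ones")
  }
  invisible(TRUE)
}

#' Default synthetic ROI layout
#'
#' Four Gaussian-blob seeds emulating the bilateral core and shell of the
#' nucleus accumbens, placed near the centre of the grid with left seeds at
#' smaller x-index. Coordinates scale with the grid so any grid of at least
#' 20 voxels per axis is usable.
#'
#' @param grid_dims integer length-3 grid size.
#' @return data.frame with columns name, cx, cy, cz, sigma.
#' @export
default_roi_layout <- function(grid_dims = c(24, 24, 24)) {
  s <- min(grid_dims) / 24
  ctr <- (grid_dims + 1) / 2
  data.frame(
    name = SEED_NAMES,
    cx = ctr[1] + s * c(-3.5, -3.5, 3.5, 3.5),
    cy = ctr[2] + s * c(-1.5, 1.5, -1.5, 1.5),
    cz = ctr[3] + s * c(0, 0, 0, 0),
    sigma = rep(1.5 * s, 4),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic probabilistic seed atlas
#'
#' Builds a spherical brain mask and Gaussian-blob probability maps
#' `p(v) = exp(-d(v, centre)^2 / (2 sigma^2))`, truncated at `trunc_radius`
#' voxels from the centre (support radius). A `sigma` of 0 yields a
#' degenerate single-voxel ROI with probability 1 at the rounded centre.
#' ROI centres are jittered by up to `jitter` voxels, drawn from `seed`, so
#' replicate atlases vary reproducibly.
#'
#' @param grid_dims integer length-3, each >= 20.
#' @param voxel_size mm per axis.
#' @param roi_layout data.frame as from [default_roi_layout()].
#' @param mask_radius brain-mask sphere radius in voxels.
#' @param trunc_radius ROI support radius in voxels.
#' @param jitter maximal uniform centre jitter in voxels.
#' @param validate check the full atlas invariants (disable for
#'   deliberately degenerate layouts, e.g. single-voxel ROIs).
#' @param seed integer RNG seed.
#' @return A validated `prob_atlas`.
#' @export
generate_atlas <- function(grid_dims = c(24, 24, 24),
                           voxel_size = c(2, 2, 2),
                           roi_layout = default_roi_layout(grid_dims),
                           mask_radius = 10 * min(grid_dims) / 24,
                           trunc_radius = 1.6 * min(grid_dims) / 24,
                           jitter = 0.3,
                           validate = TRUE,
                           seed = 1L) {
  if (any(grid_dims < 20)) stop("grid must be at least 20x20x20")
  set.seed(derive_seed(seed, "atlas"))
  ctr <- (grid_dims + 1) / 2
  brain_mask <- grid_dist2(grid_dims, ctr) <= mask_radius^2

  rois <- list()
  for (i in seq_len(nrow(roi_layout))) {
    cen <- c(roi_layout$cx[i], roi_layout$cy[i], roi_layout$cz[i]) +
      stats::runif(3, -jitter, jitter)
    sg <- roi_layout$sigma[i]
    d2 <- grid_dist2(grid_dims, cen)
    if (sg <= 0) {
      p <- array(0, grid_dims)
      p[round(cen[1]), round(cen[2]), round(cen[3])] <- 1
    } else {
      p <- exp(-d2 / (2 * sg^2))
      p[d2 > trunc_radius^2] <- 0
    }
    p[!brain_mask] <- 0
    rois[[roi_layout$name[i]]] <- p
  }

  # reject layouts whose high-probability cores collide
  nm <- names(rois)
  for (a in seq_along(nm)) {
    for (b in seq_len(a - 1L)) {
      if (any(rois[[a]] > 0.5 & rois[[b]] > 0.5)) {
        stop("invalid ROI layout: '", nm[a], "' and '", nm[b],
             "' overlap at probability > 0.5")
      }
    }
  }

  atlas <- prob_atlas(rois, brain_mask, voxel_size)
  if (validate) validate_atlas(atlas)
  atlas
}

#' Linear voxel indices of the brain mask
#' @param atlas a `prob_atlas`.
#' @return integer vector of in-mask linear indices.
#' @export
mask_indices <- function(atlas) which(atlas$brain_mask)
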