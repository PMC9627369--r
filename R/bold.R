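# Synthetic BOLD series with planted seed-target connectivity, and
# site-level location/scale effects on connectivity maps.

#' Generate one subject's synthetic BOLD series
#'
#' Every in-mask voxel receives independent Gaussian noise with SD
#' `spec$noise_sd`. Each seed ROI carries a shared unit-variance AR(1)
#' latent signal `s_k(t)`, mixed into its voxels in proportion to the
#' voxel's atlas probability. The seed's target voxels receive
#' `a_k * s_k(t)` with amplitude
#' `a_k = coupling_hc - coupling_loss_slope[k] * latent_severity`,
#' so with unit signal variance the population seed-target correlation is
#' `a / sqrt(a^2 + noise_sd^2)`. Voxels outside every ROI and target set
#' are pure noise. The draw is deterministic given `(spec$seed,
#' subject_id)`.
#'
#' Data are stored as an in-mask voxels x time matrix; [bold_to_array()]
#' reassembles the full 4D volume when NIfTI output is needed.
#'
#' @param subject one row of a cohort table.
#' @param atlas a `prob_atlas`.
#' @param spec a `simulation_spec`.
#' @param targets per-seed target voxel indices from [place_targets()].
#' @return object of class `bold_series` with fields `subject_id`, `data`
#'   (V x T matrix over mask voxels), `tr`, and `mask_idx`.
#' @export
generate_bold <- function(subject, atlas, spec, targets = place_targets(atlas, spec)) {
  stopifnot(spec$t_len >= 30)
  set.seed(derive_seed(spec$seed, paste0("bold_", subject$subject_id)))
  midx <- mask_indices(atlas)
  v <- length(midx)
  tt <- spec$t_len
  pos <- integer(prod(atlas$grid_dims))
  pos[midx] <- seq_len(v)

  data <- matrix(stats::rnorm(v * tt, sd = spec$noise_sd), v, tt)
  sev <- if (subject$group == "PD") subject$latent_severity else 0

  for (nm in names(atlas$rois)) {
    s_k <- ar1_series(tt, spec$ar_rho)
    p <- atlas$rois[[nm]]
    ridx <- which(p > 0)
    if (length(ridx)) {
      rv <- pos[ridx]
      if (!is.null(spec$seed_roi_noise_sd)) {
        data[rv, ] <- matrix(stats::rnorm(length(rv) * tt,
                                          sd = spec$seed_roi_noise_sd),
                             length(rv), tt)
      }
      data[rv, ] <- data[rv, ] + outer(p[ridx], s_k)
    }
    a <- spec$coupling_hc - spec$coupling_loss_slope[[nm]] * sev
    if (a < 0) stop("invalid spec: negative coupling amplitude for seed ", nm)
    tidx <- targets[[nm]]
    if (length(tidx) && a != 0) {
      tv <- pos[tidx]
      data[tv, ] <- data[tv, ] + a * rep(s_k, each = length(tv))
    }
  }

  structure(list(subject_id = subject$subject_id, data = data,
                 tr = spec$tr, mask_idx = midx,
                 grid_dims = atlas$grid_dims),
            class = "bold_series")
}

#' Reassemble a BOLD series as a 4D array
#'
#' Out-of-mask voxels are `NA`.
#' @param bold a `bold_series`.
#' @return numeric 4D array (x, y, z, t).
#' @export
bold_to_array <- function(bold) {
  arr <- array(NA_real_, c(bold$grid_dims, ncol(bold$data)))
  nvox <- prod(bold$grid_dims)
  for (t in seq_len(ncol(bold$data))) {
    arr[bold$mask_idx + (t - 1L) * nvox] <- bold$data[, t]
  }
  arr
}

#' Validate BOLD-series invariants
#'
#' At least 30 volumes, no non-finite values, and positive variance in
#' every in-mask voxel.
#' @param bold a `bold_series`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_bold <- function(bold) {
  if (ncol(bold$data) < 30) stop("BOLD series must have at least 30 volumes")
  if (!all(is.finite(bold$data))) stop("BOLD series contains non-finite values")
  if (any(apply(bold$data, 1, stats::var) <= 0)) {
    stop("zero-variance voxel inside the brain mask")
  }
  invisible(TRUE)
}

#' Apply site-level location/scale effects to connectivity maps
#'
#' For subject `j` at site `i`, every voxel value `z` becomes
#' `delta_i * z + gamma_i` — the multi-site structure that harmonization
#' must subsequently remove.
#'
#' @param z voxels x subjects matrix of Fisher-z values (columns aligned
#'   with `tab` rows).
#' @param tab cohort table with a `site` column.
#' @param spec a `simulation_spec` providing per-site `gamma` and `delta`.
#' @return matrix of the same shape.
#' @export
apply_site_effects <- function(z, tab, spec) {
  stopifnot(ncol(z) == nrow(tab))
  m <- match(tab$site, spec$sites$name)
  if (anyNA(m)) {
    stop("unknown site(s): ", paste(unique(tab$site[is.na(m)]), collapse = ", "))
  }
  sweep(sweep(z, 2, spec$sites$delta[m], `*`), 2, spec$sites$gamma[m], `+`)
}
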