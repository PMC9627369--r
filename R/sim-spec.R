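# Simulation specification: the study conditions the synthetic module plants.

NMS_SCORES <- c("QUIP", "MoCA", "GDS", "STAI", "apathy", "RBDSQ", "ESS", "UPSIT")

# Instrument ranges used for clipping generated scores.
SCORE_RANGES <- list(
  QUIP = c(0, 28), MoCA = c(0, 30), GDS = c(0, 15), STAI = c(20, 80),
  apathy = c(0, 4), RBDSQ = c(0, 13), ESS = c(0, 24), UPSIT = c(0, 40)
)

# Group means/SDs of the emulated two-site PD/HC cohort (clinical,
# nuisance, and subregion-volume variables). HC impulse-control and
# depression scores are degenerate at 0, as in the emulated cohort.
COHORT_PARAMS <- list(
  age      = list(pd = c(59.51, 9.40),   hc = c(60.40, 8.56),  range = c(30, 90)),
  duration = list(pd = c(3.68, 3.74),    hc = c(0, 0),         range = c(0, 30)),
  ledd     = list(pd = c(312.46, 306.92), hc = c(0, 0),        range = c(0, 3000)),
  updrs3   = list(pd = c(25.66, 12.12),  hc = c(0, 0),         range = c(0, 132)),
  hy       = list(pd = c(1.72, 0.59),    hc = c(0, 0),         range = c(0, 5)),
  QUIP     = list(pd = c(0.1034, 0.30586), hc = c(0, 0),       range = SCORE_RANGES$QUIP),
  MoCA     = list(pd = c(24.41, 4.15),   hc = c(26.03, 2.75),  range = SCORE_RANGES$MoCA),
  GDS      = list(pd = c(2.76, 2.38),    hc = c(0, 0),         range = SCORE_RANGES$GDS),
  STAI     = list(pd = c(36.03, 10.40),  hc = c(27.77, 3.99),  range = SCORE_RANGES$STAI),
  apathy   = list(pd = c(0.5603, 0.79),  hc = c(0.02, 0.14),   range = SCORE_RANGES$apathy),
  RBDSQ    = list(pd = c(4.74, 2.69),    hc = c(3.76, 1.90),   range = SCORE_RANGES$RBDSQ),
  ESS      = list(pd = c(5.56, 4.56),    hc = c(3.90, 2.34),   range = SCORE_RANGES$ESS),
  UPSIT    = list(pd = c(24.74, 9.20),   hc = c(34.43, 3.46),  range = SCORE_RANGES$UPSIT),
  vol_core_L  = list(pd = c(376.90, 47.22), hc = c(378.71, 39.29), range = c(100, 800)),
  vol_shell_L = list(pd = c(503.36, 62.30), hc = c(503.31, 46.38), range = c(150, 1000)),
  vol_core_R  = list(pd = c(296.17, 37.05), hc = c(298.91, 34.60), range = c(100, 800)),
  vol_shell_R = list(pd = c(598.93, 67.59), hc = c(600.88, 57.39), range = c(150, 1200)),
  tiv      = list(pd = c(1485.50, 137.33), hc = c(1449.29, 132.86), range = c(900, 2100)),
  gm       = list(pd = c(641.89, 57.13),  hc = c(644.44, 51.38), range = c(350, 950)),
  education = list(pd = c(12.0, 3.5),    hc = c(12.5, 3.5),     range = c(0, 25))
)

# Probability of male sex per group (59/57 PD, 45/55 HC).
P_MALE <- c(PD = 59 / 116, HC = 45 / 100)

#' Default latent-severity loadings on the clinical scores
#'
#' Per-score weight (in within-group SD units) of the single latent
#' severity factor shared with the connectivity attenuation. Signs follow
#' the direction in which each symptom worsens: depression, anxiety,
#' apathy, RBD, and sleepiness scores increase with severity; cognition
#' (MoCA) and olfaction (UPSIT) decrease.
#'
#' @return named numeric vector over the eight symptom scores.
#' @export
default_behavior_loadings <- function() {
  c(QUIP = 0.10, MoCA = -0.40, GDS = 0.60, STAI = 0.65,
    apathy = 0.60, RBDSQ = 0.35, ESS = 0.25, UPSIT = -0.30)
}

#' Build a simulation specification
#'
#' Encodes the statistical structure that the downstream analysis assumes:
#' a two-site PD/HC cohort, per-seed target regions whose connectivity to
#' the seed is attenuated in patients in proportion to a latent severity
#' factor, site-level additive/multiplicative effects on the z-maps, and
#' loadings coupling the same latent factor to the symptom scores.
#'
#' Defaults are the emulated study conditions: 116 patients and 100
#' controls split roughly 3:1 over two sites, a site offset of 1.0 and a
#' scale factor of 2 on the second site, a healthy seed-target coupling of
#' 0.45 (signal-amplitude units) lost at 0.12 per unit severity in three
#' of the four seeds (the fourth seed, `shell_R`, carries no group effect),
#' and the symptom loadings of [default_behavior_loadings()].
#'
#' @param n_pd,n_hc group sizes (each >= 2).
#' @param sites data.frame with columns name, fraction, gamma (additive
#'   offset on z), delta (scale factor on z, > 0).
#' @param coupling_hc healthy seed-target signal amplitude, in `[0, 1]`.
#' @param coupling_loss_slope named per-seed amplitude loss per unit
#'   latent severity (a scalar is recycled over seeds).
#' @param noise_sd voxel noise SD, signal units.
#' @param seed_roi_noise_sd if `NULL` (default) seed-ROI voxels share the
#'   voxel noise SD.
#' @param behavior_loadings named per-score severity weights (SD units).
#' @param severity_mean,severity_sd,severity_range truncated-normal
#'   parameters of the latent severity in patients (controls are 0).
#' @param t_len number of BOLD volumes (>= 30).
#' @param tr repetition time, seconds.
#' @param ar_rho AR(1) coefficient of the seed signal.
#' @param n_target_blobs spherical target regions per seed.
#' @param target_radius target-sphere radius, voxels (scaled with grid).
#' @param fd_threshold mean-FD exclusion threshold, mm.
#' @param seed root RNG seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_pd = 116, n_hc = 100,
                            sites = data.frame(
                              name = c("site1", "site2"),
                              fraction = c(0.75, 0.25),
                              gamma = c(0, 1.0),
                              delta = c(1, 2),
                              stringsAsFactors = FALSE),
                            coupling_hc = 0.45,
                            coupling_loss_slope = c(core_L = 0.12, shell_L = 0.12,
                                                    core_R = 0.12, shell_R = 0),
                            noise_sd = 1,
                            seed_roi_noise_sd = NULL,
                            behavior_loadings = default_behavior_loadings(),
                            severity_mean = 1.5, severity_sd = 0.6,
                            severity_range = c(0, 3),
                            t_len = 200, tr = 2, ar_rho = 0.3,
                            n_target_blobs = 2, target_radius = 2.9,
                            fd_threshold = 0.5,
                            seed = 1L) {
  stopifnot(n_pd >= 2, n_hc >= 2, t_len >= 30)
  if (abs(sum(sites$fraction) - 1) > 1e-8) stop("site fractions must sum to 1")
  if (any(sites$delta <= 0)) stop("site scale factors (delta) must be > 0")
  if (coupling_hc < 0 || coupling_hc > 1) stop("coupling_hc must lie in [0, 1]")
  if (length(coupling_loss_slope) == 1 && is.null(names(coupling_loss_slope))) {
    coupling_loss_slope <- stats::setNames(rep(coupling_loss_slope, 4), SEED_NAMES)
  }
  if (!all(SEED_NAMES %in% names(coupling_loss_slope))) {
    stop("coupling_loss_slope must name all seeds: ",
         paste(SEED_NAMES, collapse = ", "))
  }
  sev_max <- severity_range[2]
  if (coupling_hc - max(coupling_loss_slope) * sev_max < 0) {
    stop("invalid spec: coupling_hc - coupling_loss_slope * max(latent_severity) ",
         "must be >= 0 (negative coupling amplitude)")
  }
  if (!all(NMS_SCORES %in% names(behavior_loadings))) {
    stop("behavior_loadings must name all scores: ",
         paste(NMS_SCORES, collapse = ", "))
  }
  structure(
    list(n_pd = n_pd, n_hc = n_hc, sites = sites,
         coupling_hc = coupling_hc,
         coupling_loss_slope = coupling_loss_slope[SEED_NAMES],
         noise_sd = noise_sd, seed_roi_noise_sd = seed_roi_noise_sd,
         behavior_loadings = behavior_loadings[NMS_SCORES],
         severity_mean = severity_mean, severity_sd = severity_sd,
         severity_range = severity_range,
         t_len = t_len, tr = tr, ar_rho = ar_rho,
         n_target_blobs = n_target_blobs, target_radius = target_radius,
         fd_threshold = fd_threshold, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Simulation spec:", x$n_pd, "PD /", x$n_hc, "HC,",
      nrow(x$sites), "sites, T =", x$t_len, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Place per-seed target regions on the atlas grid
#'
#' Each seed receives `n_target_blobs` spherical regions whose voxels carry
#' the seed signal at the subject's coupling amplitude. Regions lie on two
#' rings above and below the seed plane, fully inside the brain mask,
#' disjoint across seeds and disjoint from every seed's support, so each
#' voxel couples to at most one seed.
#'
#' @param atlas a `prob_atlas`.
#' @param spec a `simulation_spec`.
#' @return named list (one entry per seed) of in-mask linear voxel indices.
#' @export
place_targets <- function(atlas, spec) {
  dims <- atlas$grid_dims
  s <- min(dims) / 24
  ctr <- (dims + 1) / 2
  rad <- spec$target_radius * s
  # two rings of four centres each, z offset +/- 5.5, lateral radius 4.15;
  # rotated 45 degrees against each other so all eight are >5.8 apart
  lat <- 4.15 * s; dz <- 5.5 * s
  ang_top <- c(0, 90, 180, 270) * pi / 180
  ang_bot <- c(45, 135, 225, 315) * pi / 180
  centres <- rbind(
    cbind(ctr[1] + lat * cos(ang_top), ctr[2] + lat * sin(ang_top), ctr[3] + dz),
    cbind(ctr[1] + lat * cos(ang_bot), ctr[2] + lat * sin(ang_bot), ctr[3] - dz)
  )
  if (spec$n_target_blobs * length(SEED_NAMES) > nrow(centres)) {
    stop("target layout supports at most ", nrow(centres), " regions")
  }
  roi_support <- Reduce(`|`, lapply(atlas$rois, function(p) p > 0))
  targets <- stats::setNames(vector("list", length(SEED_NAMES)), SEED_NAMES)
  k <- 0L
  for (nm in SEED_NAMES) {
    idx <- integer(0)
    for (b in seq_len(spec$n_target_blobs)) {
      k <- k + 1L
      inb <- which(grid_dist2(dims, centres[k, ]) <= rad^2 &
                     atlas$brain_mask & !roi_support)
      idx <- c(idx, inb)
    }
    targets[[nm]] <- sort(unique(idx))
  }
  ov <- unlist(targets)
  if (anyDuplicated(ov)) stop("internal error: target regions overlap across seeds")
  targets
}
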