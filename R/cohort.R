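# Synthetic cohort table and head-motion quality control.

#' Generate a synthetic subject table
#'
#' Draws a two-site PD/HC cohort whose demographic, nuisance, volumetric,
#' and clinical-score distributions follow the emulated study's group
#' summaries. A latent severity factor is drawn once per patient from a
#' truncated normal (controls are fixed at 0) and injected into every
#' clinical score through `spec$behavior_loadings`: for score `b` with
#' group mean `mu_b` and SD `sd_b`,
#' `y = mu_b + sd_b * (lambda_b * z_sev + sqrt(1 - lambda_b^2) * eps)`,
#' where `z_sev` is the standardized severity and `eps` independent
#' standard normal noise, clipped afterwards to the instrument range.
#' Control scores carry no latent component. Head motion is summarised as
#' mean framewise displacement (log-normal); `motion_flag` marks subjects
#' exceeding `spec$fd_threshold`.
#'
#' @param spec a [simulation_spec()].
#' @return data.frame of class `cohort_table`, one row per subject, with
#'   the hidden simulation ground truth in column `latent_severity`.
#' @export
generate_cohort <- function(spec) {
  set.seed(derive_seed(spec$seed, "cohort"))
  n <- spec$n_pd + spec$n_hc
  group <- c(rep("PD", spec$n_pd), rep("HC", spec$n_hc))

  # deterministic per-group site counts from the fractions
  site_of <- function(ng) {
    cuts <- diff(c(0, round(cumsum(spec$sites$fraction) * ng)))
    rep(spec$sites$name, cuts)
  }
  site <- c(site_of(spec$n_pd), site_of(spec$n_hc))

  sev <- numeric(n)
  is_pd <- group == "PD"
  sev[is_pd] <- rnorm_trunc(sum(is_pd), spec$severity_mean, spec$severity_sd,
                            spec$severity_range[1], spec$severity_range[2])
  z_sev <- (sev - spec$severity_mean) / spec$severity_sd

  tab <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    group = group, site = site,
    sex = ifelse(stats::runif(n) < P_MALE[group], "M", "F"),
    stringsAsFactors = FALSE
  )

  draw <- function(var, latent = FALSE) {
    prm <- COHORT_PARAMS[[var]]
    mu <- ifelse(is_pd, prm$pd[1], prm$hc[1])
    sd <- ifelse(is_pd, prm$pd[2], prm$hc[2])
    lam <- if (latent) spec$behavior_loadings[[var]] else 0
    y <- mu + sd * ifelse(is_pd, lam * z_sev, 0) +
      sd * ifelse(is_pd, sqrt(1 - lam^2), 1) * stats::rnorm(n)
    clip_range(y, prm$range[1], prm$range[2])
  }

  for (v in c("age", "education", "duration", "ledd", "updrs3", "hy",
              "tiv", "gm", "vol_core_L", "vol_shell_L", "vol_core_R",
              "vol_shell_R")) {
    tab[[v]] <- draw(v)
  }
  for (v in NMS_SCORES) tab[[v]] <- draw(v, latent = TRUE)

  # PD-only variables are exactly 0 in controls
  for (v in c("duration", "ledd", "updrs3", "hy")) tab[[v]][!is_pd] <- 0

  tab$mean_fd <- stats::rlnorm(n, meanlog = log(0.15), sdlog = 0.5)
  tab$motion_flag <- tab$mean_fd > spec$fd_threshold
  tab$latent_severity <- sev

  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Validate cohort-table invariants
#'
#' Clinical scores must lie within their instrument ranges, control rows
#' must have zero disease duration and medication dose, and mean framewise
#' displacement must be non-negative.
#'
#' @param tab a cohort table.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_cohort <- function(tab) {
  for (v in NMS_SCORES) {
    rg <- SCORE_RANGES[[v]]
    if (any(tab[[v]] < rg[1] - 1e-9 | tab[[v]] > rg[2] + 1e-9)) {
      stop("score '", v, "' outside instrument range [",
           rg[1], ", ", rg[2], "]")
    }
  }
  hc <- tab$group == "HC"
  if (any(tab$duration[hc] != 0) || any(tab$ledd[hc] != 0)) {
    stop("HC rows must have duration = ledd = 0")
  }
  if (any(tab$mean_fd < 0)) stop("mean_fd must be >= 0")
  invisible(TRUE)
}

#' Exclude subjects for excessive head motion
#'
#' Filters the cohort either on an explicit boolean `motion_flag` column
#' (`criterion = "flag"`, the default, which lets an externally supplied
#' exclusion manifest be reproduced exactly) or on a mean framewise
#' displacement threshold (`criterion = "fd"`, default 0.5 mm).
#'
#' @param tab a cohort table.
#' @param criterion `"flag"` or `"fd"`.
#' @param fd_threshold mm, used when `criterion = "fd"`.
#' @return The retained rows, with an `exclusions` attribute giving the
#'   per-group excluded counts. Excluding every subject yields an empty
#'   table with a warning, not an error.
#' @export
qc_filter <- function(tab, criterion = c("flag", "fd"), fd_threshold = 0.5) {
  criterion <- match.arg(criterion)
  drop <- switch(criterion,
    flag = {
      if (is.null(tab$motion_flag)) stop("cohort table has no 'motion_flag' column")
      as.logical(tab$motion_flag)
    },
    fd = {
      if (is.null(tab$mean_fd)) stop("cohort table has no 'mean_fd' column")
      tab$mean_fd > fd_threshold
    }
  )
  if (anyNA(drop)) stop("motion criterion is not resolvable for every row")
  excl <- table(factor(tab$group[drop], levels = unique(tab$group)))
  out <- tab[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all subjects excluded by the motion criterion")
  message("qc_filter: excluded ", paste(sprintf("%d %s", excl, names(excl)),
                                        collapse = ", "),
          "; retained ", nrow(out), " subjects")
  attr(out, "exclusions") <- excl
  out
}
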