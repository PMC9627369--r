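# End-to-end pipeline: simulate -> fc -> harmonize -> glm -> pls,
# reproducible from a single configuration object.

#' Build a pipeline configuration
#'
#' A single document of every stage parameter; all randomness derives
#' from `seed`, so identical configurations reproduce identical numbers.
#'
#' @param spec a [simulation_spec()] (its `seed` is overridden by `seed`).
#' @param seed root seed for the whole run.
#' @param qc_criterion `"flag"` or `"fd"` for [qc_filter()].
#' @param combat_preserve covariates preserved by harmonization.
#' @param glm_covariates nuisance covariates of the group contrast.
#' @param q FDR level; `k_min` cluster-extent threshold (voxels);
#'   `connectivity` 6/18/26.
#' @param behaviors behaviour columns of the PLS Y block.
#' @param pls_nuisance nuisance columns residualized from both blocks in
#'   the rerun (the seed's own volume column is appended per seed).
#' @param first_pass also run the extended-block PLS (behaviours plus
#'   nuisance variables in Y) before the residualized rerun.
#' @param n_perm,n_boot resampling sizes.
#' @param run_bootstrap run bootstrap inference; disable when only
#'   latent-variable significance is needed (e.g. replicate studies).
#' @param stages named logical toggles (`simulate`, `fc`, `harmonize`,
#'   `glm`, `pls`).
#' @param out_dir optional output directory; when set, stage outputs are
#'   written (NIfTI-1 maps, TSV tables, JSON manifest).
#' @param keep_fc retain the per-seed z-map matrices in the result.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = simulation_spec(),
                            seed = 1L,
                            qc_criterion = "flag",
                            combat_preserve = c("group", "age", "sex", "education"),
                            glm_covariates = c("sex", "age", "education", "mean_fd"),
                            q = 0.05, k_min = 20, connectivity = 26,
                            behaviors = NMS_SCORES,
                            pls_nuisance = c("age", "education", "duration",
                                             "ledd", "updrs3", "hy", "tiv", "gm"),
                            first_pass = FALSE,
                            n_perm = 1000, n_boot = 1000,
                            run_bootstrap = TRUE,
                            stages = c(simulate = TRUE, fc = TRUE,
                                       harmonize = TRUE, glm = TRUE, pls = TRUE),
                            out_dir = NULL, keep_fc = FALSE) {
  stopifnot(q > 0, q < 1, k_min >= 1)
  spec$seed <- as.integer(seed)
  structure(
    list(spec = spec, seed = as.integer(seed), qc_criterion = qc_criterion,
         combat_preserve = combat_preserve, glm_covariates = glm_covariates,
         q = q, k_min = k_min, connectivity = connectivity,
         behaviors = behaviors, pls_nuisance = pls_nuisance,
         first_pass = first_pass, n_perm = n_perm, n_boot = n_boot,
         run_bootstrap = run_bootstrap,
         stages = stages, out_dir = out_dir, keep_fc = keep_fc),
    class = "pipeline_config"
  )
}

# 0/1 design matrix from cohort columns (sex/group coded by factor level)
.design_from_cohort <- function(cohort, columns) {
  if (!length(columns)) return(NULL)
  out <- lapply(columns, function(cv) {
    col <- cohort[[cv]]
    if (is.null(col)) stop("covariate '", cv, "' not in cohort table")
    if (cv == "group") return(as.numeric(col == "PD"))
    if (is.character(col) || is.factor(col)) return(as.numeric(factor(col)) - 1)
    as.numeric(col)
  })
  m <- do.call(cbind, out)
  colnames(m) <- columns
  m
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes the enabled stages in order: cohort/atlas simulation with QC
#' filtering; per-subject seed connectivity mapping (Fisher z) with site
#' effects applied; empirical-Bayes harmonization; voxelwise group
#' contrasts with FDR and cluster-extent thresholding; and, for every
#' seed with a non-empty significance mask, the behavioural PLS
#' correlation on patients only, residualizing the nuisance set from both
#' blocks. Seeds whose mask is empty are skipped with a message
#' (recorded in the manifest). A manifest entry per stage records
#' parameters, derived seeds, and summary counts; reruns with an
#' identical configuration reproduce identical numbers.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `atlas`,
#'   `targets`, `cohort`, `cohort_qc`, `fc` (if kept), `combat_model`,
#'   `glm`, `masks`, `pls_first`, `pls`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  on_stage <- function(s) isTRUE(config$stages[[s]])
  manifest <- list(config_seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(stage = stage), list(...))
  }
  result <- list(manifest = NULL)

  if (!on_stage("simulate")) {
    manifest$stages <- manifest$stages %||% list()
    result$manifest <- manifest
    class(result) <- "pipeline_result"
    return(result)
  }

  ## -- simulate ------------------------------------------------------
  atlas <- generate_atlas(seed = spec$seed)
  targets <- place_targets(atlas, spec)
  cohort <- generate_cohort(spec)
  cohort_qc <- suppressMessages(qc_filter(cohort, criterion = config$qc_criterion,
                                          fd_threshold = spec$fd_threshold))
  note("simulate", n_pd = sum(cohort_qc$group == "PD"),
       n_hc = sum(cohort_qc$group == "HC"),
       excluded = as.list(attr(cohort_qc, "exclusions")),
       seed = spec$seed)
  result$atlas <- atlas; result$targets <- targets
  result$cohort <- cohort; result$cohort_qc <- cohort_qc
  midx <- mask_indices(atlas)

  if (!on_stage("fc")) { result$manifest <- manifest; class(result) <- "pipeline_result"; return(result) }

  ## -- fc ------------------------------------------------------------
  n <- nrow(cohort_qc)
  zmaps <- lapply(SEED_NAMES, function(nm) matrix(NA_real_, length(midx), n))
  names(zmaps) <- SEED_NAMES
  for (j in seq_len(n)) {
    bold <- generate_bold(cohort_qc[j, ], atlas, spec, targets)
    zj <- fc_all_seeds(bold, atlas)
    for (nm in SEED_NAMES) zmaps[[nm]][, j] <- zj[, nm]
  }
  for (nm in SEED_NAMES) {
    colnames(zmaps[[nm]]) <- cohort_qc$subject_id
    zmaps[[nm]] <- apply_site_effects(zmaps[[nm]], cohort_qc, spec)
  }
  note("fc", n_subjects = n, n_voxels = length(midx), t_len = spec$t_len)

  if (!on_stage("harmonize")) {
    if (config$keep_fc) result$fc <- zmaps
    result$manifest <- manifest; class(result) <- "pipeline_result"; return(result)
  }

  ## -- harmonize -----------------------------------------------------
  design <- .design_from_cohort(cohort_qc, config$combat_preserve)
  combat_models <- list()
  for (nm in SEED_NAMES) {
    h <- suppressMessages(harmonize(zmaps[[nm]], cohort_qc$site, design))
    zmaps[[nm]] <- h$data
    combat_models[[nm]] <- h$model
  }
  note("harmonize", preserve = config$combat_preserve,
       sites = unique(cohort_qc$site))
  result$combat_model <- combat_models
  if (config$keep_fc) result$fc <- zmaps

  if (!on_stage("glm")) { result$manifest <- manifest; class(result) <- "pipeline_result"; return(result) }

  ## -- glm -----------------------------------------------------------
  glms <- masks <- list()
  for (nm in SEED_NAMES) {
    gr <- suppressMessages(voxelwise_group_contrast(
      zmaps[[nm]], cohort_qc, covariates = config$glm_covariates,
      seed_name = nm))
    fdr <- fdr_correct(gr$p, q = config$q)
    msk <- cluster_extent_filter(fdr$reject, k_min = config$k_min,
                                 connectivity = config$connectivity,
                                 seed_name = nm, q = config$q,
                                 mask_idx = midx, grid_dims = atlas$grid_dims)
    gr$p_adj <- fdr$p_adj
    glms[[nm]] <- gr
    masks[[nm]] <- msk
  }
  note("glm", covariates = config$glm_covariates, q = config$q,
       k_min = config$k_min, connectivity = config$connectivity,
       n_sig_voxels = vapply(masks, function(m) sum(m$mask), 0L))
  result$glm <- glms; result$masks <- masks

  if (!on_stage("pls")) { result$manifest <- manifest; class(result) <- "pipeline_result"; return(result) }

  ## -- pls -----------------------------------------------------------
  pd <- cohort_qc$group == "PD"
  pls_first <- pls <- list()
  skipped <- character(0)
  for (nm in SEED_NAMES) {
    vox <- match(which(masks[[nm]]$mask), midx)
    if (length(vox) == 0) {
      message("run_pipeline: seed '", nm,
              "' has an empty significance mask; PLS skipped")
      skipped <- c(skipped, nm)
      next
    }
    X <- t(zmaps[[nm]][vox, pd, drop = FALSE])
    keep_rows <- !apply(X, 1, anyNA)
    Y_beh <- as.matrix(cohort_qc[pd, config$behaviors, drop = FALSE])
    keep_rows <- keep_rows & !apply(Y_beh, 1, anyNA)
    if (sum(!keep_rows) > 0) {
      message("run_pipeline: dropping ", sum(!keep_rows),
              " patient(s) with missing values (listwise)")
    }
    X <- X[keep_rows, , drop = FALSE]
    Y_beh <- Y_beh[keep_rows, , drop = FALSE]
    pdtab <- cohort_qc[pd, , drop = FALSE][keep_rows, , drop = FALSE]
    nuis_cols <- c(config$pls_nuisance, paste0("vol_", nm))
    nuis <- .design_from_cohort(pdtab, nuis_cols)
    pls_seed <- derive_seed(config$seed, paste0("pls_", nm))

    run_one <- function(Xb, Yb) {
      if (config$run_bootstrap) {
        plsc_run(Xb, Yb, n_perm = config$n_perm, n_boot = config$n_boot,
                 seed = pls_seed)
      } else {
        fit <- plsc_fit(Xb, Yb)
        perm <- permutation_test(Xb, Yb, n_perm = config$n_perm,
                                 seed = pls_seed)
        structure(c(fit, list(perm_p = perm$perm_p)), class = "plsc_analysis")
      }
    }
    if (config$first_pass) {
      ext_cols <- unique(c(config$behaviors, "sex", nuis_cols))
      Y_ext <- .design_from_cohort(pdtab, ext_cols)
      pls_first[[nm]] <- run_one(X, Y_ext)
    }
    Xr <- residualize(X, nuis)
    Yr <- residualize(Y_beh, nuis)
    pls[[nm]] <- run_one(Xr, Yr)
  }
  note("pls", analyzed = setdiff(names(masks)[vapply(masks, function(m) sum(m$mask) > 0, TRUE)], skipped),
       skipped_empty_mask = skipped,
       n_perm = config$n_perm, n_boot = config$n_boot,
       nuisance = config$pls_nuisance)
  result$pls_first <- pls_first
  result$pls <- pls
  result$manifest <- manifest
  class(result) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    .write_pipeline_outputs(result, config)
    result$manifest$outputs <- .manifest_hashes(config$out_dir)
  }
  result
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- result$atlas
  midx <- mask_indices(atlas)
  write_atlas(atlas, file.path(config$out_dir, "atlas"))
  write_cohort(result$cohort_qc, file.path(config$out_dir, "cohort_qc.tsv"))
  for (nm in names(result$glm %||% list())) {
    write_nifti_map(result$glm[[nm]]$t, file.path(config$out_dir,
                    paste0(nm, "_tmap.nii")), midx, atlas$grid_dims,
                    atlas$voxel_size)
    write_nifti_map(result$masks[[nm]]$mask * 1,
                    file.path(config$out_dir, paste0(nm, "_mask.nii")),
                    voxel_size = atlas$voxel_size)
    utils::write.table(cluster_table(result$masks[[nm]], result$glm[[nm]], midx),
                       file.path(config$out_dir, paste0(nm, "_clusters.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(result$pls %||% list())) {
    p <- result$pls[[nm]]
    vox <- match(which(result$masks[[nm]]$mask), midx)
    bsr1 <- rep(NA_real_, length(midx))
    bsr1[vox] <- p$bootstrap_ratios[, 1]
    write_nifti_map(bsr1, file.path(config$out_dir, paste0(nm, "_bsr_lv1.nii")),
                    midx, atlas$grid_dims, atlas$voxel_size)
    scores <- data.frame(subject_id = rownames(p$imaging_scores) %||%
                           seq_len(nrow(p$imaging_scores)),
                         imaging_lv1 = p$imaging_scores[, 1],
                         behavioral_lv1 = p$behavioral_scores[, 1])
    utils::write.table(scores, file.path(config$out_dir, paste0(nm, "_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_file(
      list(seed = nm, singular_values = p$singular_values,
           cov_explained = p$cov_explained, perm_p = p$perm_p,
           score_correlation = p$score_correlation,
           loadings = as.data.frame(p$loadings),
           loading_ci_lower = as.data.frame(p$loading_ci_lower),
           loading_ci_upper = as.data.frame(p$loading_ci_upper)),
      file.path(config$out_dir, paste0(nm, "_pls.json")))
  }
  write_json_file(result$manifest, file.path(config$out_dir, "manifest.json"))
  invisible(NULL)
}

.manifest_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  as.list(h)
}

#' Human-readable pipeline report
#'
#' One block per analysed seed: network-mask size, LV-I covariance
#' explained, permutation p, significant behaviours with loadings and
#' CIs, and the imaging-behaviour score correlation. Seeds without
#' surviving voxels are listed in an explicit "no significant seeds"
#' section. Regenerating the report from the same result is
#' byte-identical.
#'
#' @param result a `pipeline_result`.
#' @param file optional path; when given the lines are written there.
#' @return character vector of report lines, invisibly when written.
#' @export
write_report <- function(result, file = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  lines <- c("Seed-based FC / behavioural PLS pipeline report",
             "================================================", "")
  analyzed <- names(result$pls %||% list())
  empty <- setdiff(names(result$masks %||% list()), analyzed)
  if (!length(analyzed)) {
    lines <- c(lines, "No significant seeds:",
               "  no seed survived FDR + cluster-extent thresholding;",
               "  PLS was not run.")
  }
  for (nm in analyzed) {
    p <- result$pls[[nm]]
    msk <- result$masks[[nm]]
    sig_b <- rownames(p$loadings)[p$loading_significant[, 1]]
    lines <- c(lines,
      sprintf("Seed %s", nm),
      sprintf("  network mask: %d voxels in %d cluster(s)",
              sum(msk$mask), length(msk$sizes)),
      sprintf("  LV-I: %.0f%% of covariance, permutation p = %.4g",
              100 * p$cov_explained[1], p$perm_p[1]),
      sprintf("  imaging-behaviour score correlation r = %.2f",
              p$score_correlation[1]),
      if (length(sig_b)) {
        c("  significant behaviours (95% bootstrap CI excludes 0):",
          vapply(sig_b, function(b) {
            sprintf("    %-6s R = %+.2f  [%.2f, %.2f]", b,
                    p$loadings[b, 1], p$loading_ci_lower[b, 1],
                    p$loading_ci_upper[b, 1])
          }, ""))
      } else "  no significant behaviours",
      "")
  }
  if (length(empty)) {
    lines <- c(lines, "Seeds without significant group differences (PLS skipped):",
               paste0("  ", empty), "")
  }
  lines <- unname(lines)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
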