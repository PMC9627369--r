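---
title: "Methods: seed connectivity, harmonization, and behavioural PLS"
author: "seedpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed connectivity, harmonization, and behavioural PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`seedpls` implements the full statistical chain used to relate seed-based
resting-state functional connectivity (FC) of striatal subregions — the
bilateral core and shell of the nucleus accumbens — to non-motor symptom
(NMS) phenotypes in Parkinson's disease: FC mapping, multi-site
harmonization, voxelwise group inference, and behavioural partial least
squares correlation (PLSC) with permutation and bootstrap inference.
Patient imaging data of this kind are access-restricted, so the package
ships a first-class synthetic-data module that plants the exact
statistical structure the analysis chain assumes; every stage is tested
end to end against that known ground truth. fMRI preprocessing
(realignment, normalization, smoothing) and anatomical segmentation are
out of scope: inputs are assumed preprocessed, and regional volumes
enter as table columns.

## The analysis model

**FC mapping.** For each subject and seed, the reference time course is
the probability-weighted mean of the seed's voxel series,
$\bar x(t) = \sum_v p_v x_v(t) / \sum_v p_v$ (the atlas is
probabilistic, so voxels contribute in proportion to membership; a
0.5-binarized mode exists for sensitivity checks). Every in-mask voxel
is correlated with the reference (Pearson r over T volumes) and mapped
through the variance-stabilizing Fisher transform $z = \mathrm{atanh}(r)$,
clipping $|r| \ge 1 - 10^{-7}$ first. Out-of-mask and zero-variance
voxels carry a missing marker (`NA`/`NaN`) through every later stage —
they are excluded from model fits, never zero-filled or imputed.

**Harmonization.** Multi-site z-maps are adjusted with the parametric
empirical-Bayes location/scale model (the canonical ComBat formulation):
$y_{ijg} = \alpha_g + X_j\beta_g + \gamma_{ig} + \delta_{ig}\varepsilon_{ijg}$
per voxel $g$, site $i$, subject $j$. Features are standardized by the
covariate fit and pooled residual SD; per-site location and scale
estimates are shrunk toward normal / inverse-gamma priors with
method-of-moments hyperparameters and iterative conditional updates
(tolerance $10^{-4}$, at most 200 iterations). The design preserves
group, age, sex, and education — preserving group keeps the effect of
interest out of the site adjustment. Harmonization operates on
subject-level z-maps (features = voxels), the unit that enters group
analysis; the between-subject SD of such features at T = 200 is roughly
0.07–0.3, the scale on which the package's Monte-Carlo checks are run.
A single-site input bypasses harmonization with a message.

**Group inference.** Per voxel, ordinary least squares of z on
[intercept, group, sex, age, education, mean FD] yields a t statistic
for the group term (contrast PD − HC; the test is two-sided — the
direction of change is an empirical outcome, not an assumption).
Multiplicity is controlled per seed map by Benjamini–Hochberg FDR at
q = 0.05 (four seed families, matching per-seed reporting), then a
cluster-extent threshold of 20 voxels is applied to the rejection set —
FDR first, extent second, the conventional reading of that combination.
Cluster connectivity defaults to the 26-neighbourhood and is
configurable (6/18/26); the choice only matters for marginal, scattered
rejections. Seeds with no surviving voxels produce an empty mask and
are excluded from PLSC with a logged notice. Subregion volumes are
compared by ANCOVA (partial F for group, adjusting age, sex,
education), which reduces exactly to one-way ANOVA without covariates.

**Behavioural PLSC.** For each surviving seed network, the imaging
block X (patients × in-mask significant voxels, Fisher z) and the
behaviour block Y (patients × scores) are column z-scored
(denominator n − 1) and the cross-block correlation
$R = Y_z^\top X_z/(n-1)$ decomposed as $R = USV^\top$. Each latent
variable (LV) pairs a behavioural salience column of U with an imaging
salience column of V; covariance explained is $s_i^2/\sum_j s_j^2$, and
composite scores are $X_zV$ (imaging) and $Y_zU$ (behavioural). PLSC is
fit on patients only: several control scores are degenerate at zero, so
a pooled fit would be driven by the group contrast rather than
within-patient covariation.

*Significance.* Rows of Y are permuted as a block (N = 1000 by
default) and each permuted singular value compared with the observed
one at the same LV position, without rotation — the canonical
behavioural-PLSC convention; $p_i = (1 + \#\{s_i^{perm} \ge
s_i^{obs}\})/(1 + N)$.

*Reliability.* Subjects are resampled with replacement (paired rows),
each resample's decomposition aligned to the observed one by Procrustes
rotation of the behavioural saliences. Voxel bootstrap ratios are
computed on singular-value-weighted saliences,
$\mathrm{BSR}_v = (vs)_v^{obs} / \mathrm{SD}_{boot}((vs)_v)$ — the
scale on which the ratio is approximately standard normal under the
null; unit-norm saliences would anti-conservatively inflate the ratio
several-fold. Null calibration is evaluated at the pipeline's block
shape (about 200 network voxels and 8 scores at n = 100 patients),
where the rejection rate at |BSR| > 3.3 is well under 1%; with much
narrower imaging blocks (tens of voxels) the Procrustes alignment
makes the ratio mildly anti-conservative, up to about 1%. |BSR| > 3.3 flags reliable voxels (a two-sided
normal tail of ≈ 0.001). Behavioural loadings are Pearson correlations
between each score and the LV's imaging composite, recomputed per
resample; a loading is significant when its 95% percentile CI excludes
zero. Percentile (not bias-corrected) intervals are used; zero-SD
degeneracies cap the BSR at 10^6; resamples that lose all variance in
a column are redrawn (at most 50 times, counted).

*Sign convention.* The largest-magnitude element of each U column is
made positive, flipping U and V together — results are invariant to the
SVD's arbitrary sign, and score correlations are unaffected by a joint
flip.

*Nuisance-specific rerun.* To isolate the NMS association from
disease-severity and morphometric covariates, the analysis is run
twice: once with an extended behaviour block, then again on the eight
NMS scores after residualizing age, education, disease duration, LEDD,
UPDRS-III, H&Y stage, the seed's own subregion volume, TIV, and grey
matter volume from *both* blocks (each column replaced by its OLS
residual on [intercept, nuisance]). Removing nuisance from the
association requires removing it from both sides; a single-block mode
exists. Listwise deletion handles missing behaviour values, with a
logged count.

*Random streams.* One root seed; permutation, bootstrap, and every
per-subject simulation stream derive independent sub-seeds through a
31-bit label hash, so results are reproducible and independent of
execution order.

## What the synthetic-data module emulates

The generator plants precisely the structure the chain is built to
detect, with defaults chosen as the emulated study's conditions:

- **Cohort.** 116 patients / 100 controls after QC (generated as
  129/106 minus flagged subjects when the flag column is used), split
  ~3:1 over two sites. Demographics, nuisance variables, subregion
  volumes, and the eight clinical scores (QUIP, MoCA, GDS, STAI,
  apathy, RBD-SQ, ESS, UPSIT) are drawn from the published group
  means/SDs and clipped to instrument ranges; patient-only variables
  are exactly zero in controls. Education is not tabulated in the
  source cohort and is set to a plausible 12 ± 3.5 years.
- **Latent coupling.** One latent severity factor per patient
  (truncated normal, mean 1.5, SD 0.6 on [0, 3]; controls 0) drives
  both blocks — a rank-1 coupling, because the emulated study reports a
  single significant LV per seed. Clinical scores receive the
  standardized factor through per-score loadings (defaults 0.60–0.65
  for depression/anxiety/apathy, negative for cognition and olfaction,
  smaller for sleep scores — magnitudes that reproduce behavioural
  loadings in the published 0.2–0.75 range at n ≈ 100); connectivity
  amplitude falls as `coupling_hc − slope × severity` with
  `coupling_hc = 0.45` and slope 0.12 in three of the four seeds. The
  right shell carries no group effect, so the pipeline should find —
  and in tests does find — no surviving network there, mirroring the
  asymmetric result the chain must be able to reproduce.
- **BOLD.** Unit-variance Gaussian AR(1) seed signals (ρ = 0.3, the
  simplest process with BOLD-like smoothness; the closed-form
  population correlation `a/sqrt(a² + σ²)` still holds), i.i.d.
  Gaussian voxel noise (σ = 1), T = 200 volumes at TR = 2 s. Seed ROI
  voxels mix the signal in proportion to atlas probability; each seed's
  two spherical target regions (~200 voxels, large enough to survive
  the 20-voxel extent threshold) receive it at the subject's coupling
  amplitude; everything else is pure noise.
- **Sites.** Site 2 applies `z' = 2 z + 1` — an additive offset of 1.0
  and a variance ratio of 4, large against the z-map scale, which the
  harmonization stage must remove.
- **Atlas.** A 24³ synthetic grid (not MNI; the pipeline is
  grid-agnostic) with a spherical brain mask and four Gaussian-blob
  seeds (σ = 1.5 voxels, support truncated at 1.9 voxels so that
  jittered seeds can never share support — cross-seed signal leakage
  would otherwise put a spurious group effect into the null seed's
  reference).

**What it does not emulate** — and hence what passing tests do not
show about real data: hemodynamic response shapes, physiological and
motion artefacts in image space, spatial autocorrelation of noise,
integer-valued clinical scales (scores are continuous and clipped),
non-Gaussian score distributions, site-by-effect interactions, and
registration error. The plant-detect closure demonstrates the
*statistical machinery* is correct and calibrated, not that real
effects of this size exist.

## Numerical and design choices

- Head-motion exclusion: the exact criterion of the emulated study is
  in unavailable supplementary material, so `qc_filter()` accepts
  either an explicit boolean flag column (which reproduces published
  exclusion counts exactly) or a mean-FD threshold, default 0.5 mm — a
  common convention.
- Whether the original analysis z-scored or merely centred the voxel
  block before the cross-block product is unstated; both blocks are
  z-scored here, which makes R a correlation matrix, consistent with
  reporting correlation coefficients. This is the package's choice,
  not a claim about the original implementation. Likewise BH was
  chosen for the unnamed FDR variant, and binary sex enters the
  extended Y block as a 0/1 column.
- Permutation compares singular values by LV position without
  Procrustes rotation; the bootstrap uses rotation. Rationale: the
  canonical behavioural-PLSC convention for each.
- Degenerate inputs: constant references error; zero-variance voxels
  go missing with a warning; zero-variance PLS columns error naming
  the columns; rank-deficient designs error naming collinear columns;
  an all-excluded QC table warns and returns an empty table.
- Problem sizes in the shipped tests — n = 100/group, T = 200, a 24³
  grid, 500 permutations/bootstraps, and 20 replicate simulations for
  the plant-detect closure — are the package's reduced desk scale: one
  replicate of the full chain runs in seconds while leaving planted
  effects at realistic detectability (per-subject Fisher-z sampling SD
  ≈ 1/√(T−3) ≈ 0.07 against planted z differences ≈ 0.17).
- NIfTI-1 output uses a diagonal affine with the voxel size;
  uncompressed `.nii` is the default so that reruns are byte-identical
  (gzip embeds timestamps). Voxel indices in tables are 1-based, the
  R array convention, and documented as such.

## Known limitations

The EB shrinkage of harmonization leaves a small residual site
difference per feature (the price of shrinkage; at the shipped scales
it is an order of magnitude below the 0.05 acceptance band, and the
implementation is verified to numerical identity against the reference
`sva::ComBat`). Harmonization is not exactly idempotent; on null
simulations at the pipeline's scale a second pass moves values by
< 10⁻³ RMS. PLSC permutation p-values are position-matched, which can
be conservative for later LVs when earlier ones are strong. The
bootstrap CI is percentile, not BCa; with very small n it can
undercover. None of the non-parametric ComBat, ComBat-GAM,
longitudinal variants, PLS regression, sparse PLS, or split-half
stability analyses are implemented.
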