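# seedpls

Seed-based functional connectivity and behavioural partial least squares
correlation, as one reproducible pipeline.

## The problem

In Parkinson's disease, non-motor symptoms (NMS) — depression, anxiety,
apathy, cognitive decline, REM-sleep behaviour disorder, daytime
sleepiness, hyposmia, impulse-control problems — co-occur, and their
neural substrate in the ventral striatum is studied by correlating
resting-state functional connectivity (FC) of nucleus accumbens
subregions (bilateral core and shell) with batteries of clinical
scores. The statistical chain this requires is long: seed FC mapping,
harmonization of multi-site scanner effects, voxelwise group inference
with multiplicity control, and a multivariate brain–behaviour model
with resampling-based significance and reliability. `seedpls`
implements the whole chain for R users, together with a synthetic-data
generator that plants a known ground truth, so the machinery can be
validated end to end without access-restricted patient MRI.

## The model

For each subject and seed the FC map is the Fisher-transformed Pearson
correlation, z = atanh(r), between the probability-weighted seed
reference time course and every in-brain voxel. Site effects are
removed with the parametric empirical-Bayes location/scale model
(ComBat): y = α + Xβ + γ<sub>site</sub> + δ<sub>site</sub>ε, preserving
group, age, sex, and education. Voxelwise two-sided group contrasts
(OLS with nuisance covariates) are thresholded at Benjamini–Hochberg
FDR q = 0.05 with a 20-voxel cluster-extent filter; surviving voxels
define each seed's disease-related network.

Within patients, the network matrix X (subjects × voxels) and score
matrix Y (subjects × behaviours) are z-scored and the cross-block
correlation R = Y′X/(n−1) is decomposed by SVD, R = USV′. Each latent
variable (LV) pairs behavioural saliences (U) with imaging saliences
(V); covariance explained is s²ᵢ/Σs²ⱼ. LV significance comes from 1000
permutations of Y's rows; voxel reliability from 1000 paired bootstrap
resamples via bootstrap ratios on singular-value-weighted saliences
(|BSR| > 3.3 ≈ p < 0.001); behavioural loadings are correlations of
each score with the LV imaging composite, significant when the 95%
percentile bootstrap CI excludes zero. The analysis is rerun after
residualizing age, education, disease duration, LEDD, UPDRS-III, H&Y,
subregion volume, TIV, and grey-matter volume from both blocks, which
isolates the NMS-specific association.

## Worked example

Simulate a two-site cohort (60 patients / 60 controls here, to keep the
example quick), run every stage, and print the report:

```r
library(seedpls)
spec <- simulation_spec(n_pd = 60, n_hc = 60, t_len = 120, seed = 7)
cfg  <- pipeline_config(spec = spec, seed = 7, n_perm = 500, n_boot = 500)
res  <- run_pipeline(cfg)
cat(write_report(res), sep = "\n")
```

```
Seed-based FC / behavioural PLS pipeline report
================================================

Seed core_L
  network mask: 208 voxels in 1 cluster(s)
  LV-I: 91% of covariance, permutation p = 0.001996
  imaging-behaviour score correlation r = 0.85
  significant behaviours (95% bootstrap CI excludes 0):
    MoCA   R = -0.39  [-0.58, -0.17]
    GDS    R = +0.69  [0.55, 0.82]
    STAI   R = +0.79  [0.69, 0.87]
    apathy R = +0.48  [0.34, 0.61]
    RBDSQ  R = +0.39  [0.17, 0.55]
    ESS    R = +0.25  [0.02, 0.46]
    UPSIT  R = -0.53  [-0.66, -0.36]

...(shell_L and core_R follow)...

Seeds without significant group differences (PLS skipped):
  shell_R
```

Reading the output: the generator plants connectivity loss coupled to a
latent severity factor in three of the four seeds, and the pipeline
recovers exactly those three — each with one significant latent
variable (permutation p = 1/501, the smallest value 500 permutations
allow), a ~200-voxel network matching the planted target regions, and
behavioural loadings whose signs follow the planted directions (worse
severity: higher depression/anxiety/apathy scores, lower cognition and
olfaction scores). The untouched right shell yields no surviving
voxels and is skipped, the asymmetry the chain must be able to report.
The imaging–behaviour score correlation r is the per-patient agreement
between the two composite scores.

`run_pipeline(pipeline_config(..., out_dir = "run/"))` additionally
writes NIfTI t-maps, network masks, and BSR maps, TSV score tables, a
JSON PLS result per seed, and a manifest with md5 sums; reruns with the
same configuration are byte-identical. A thin command-line wrapper
lives at `inst/scripts/run-pipeline.R`.

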