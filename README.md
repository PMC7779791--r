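# tepnet

TMS-evoked potentials (TEPs) as biomarkers of white-matter network
integrity: simulation, preprocessing, feature extraction and
cross-validated evaluation, in one tested R package.

## What problem this solves, and for whom

A TMS pulse over motor cortex evokes a stereotyped EEG response whose
shape and history-dependence reflect the integrity of the white-matter
(WM) networks carrying it. Clinical neurophysiology groups use four
scalar summaries of the 20–300 ms TEP, per regional electrode hotspot, as
cheap bedside proxies for WM microstructure otherwise measured by
diffusion MRI:

* **EPD / LPD** — OLS slopes of the single-pulse TEP over 60–100 ms and
  100–180 ms (µV/ms),
* **WFA** — adherence (Pearson correlation) of the full TEP to a
  normative healthy template,
* **STP** — the short-term plasticity index
  `(MFP_single − MFP_i) / (MFP_single + MFP_i)`, where MFP is the mean
  rectified amplitude of the single-pulse and 1 Hz inhibitory-protocol
  responses.

`tepnet` implements the full chain for methods researchers who need a
reproducible, testable reference: a seeded synthetic-cohort generator
with linked per-tract fractional anisotropy (FA) tables; epoch
preprocessing (100 µV peak-to-peak rejection, zero-phase 0.5–45 Hz FIR,
baseline correction, hotspot averaging); the four measures; pooled
t-tests with Bonferroni–Holm correction; linear-SVM classification of
injured vs healthy under 50 permutations of stratified 5-fold CV with
vertically averaged ROC; and per-ROI cross-validated linear prediction of
mean FA reported as Pearson r and RMSE. Everything is driven by one seed
and reproduces byte-for-byte.

## Worked example

```r
library(tepnet)

cfg <- sim_config(n_healthy = 20, n_injured = 20, epochs_per_condition = 20,
                  sampling_rate = 500, severity_mean = 0.6, severity_sd = 0.2,
                  noise_sd = 1, seed = 7)
coh <- simulate_cohort(cfg)            # epochs + FA table + latent severities
pp  <- preprocess_epochs(coh$epochs)   # reject -> FIR -> baseline -> hotspots

# normative template from a disjoint healthy reference cohort
ref_cfg <- cfg; ref_cfg$n_healthy <- 10L; ref_cfg$n_injured <- 0L; ref_cfg$seed <- 99L
ref_tep <- preprocess_epochs(simulate_cohort(ref_cfg)$epochs)$tep
ref_tep$subjects <- paste0("ref_", ref_tep$subjects)   # ids must stay disjoint
names(ref_tep$groups) <- ref_tep$subjects
dimnames(ref_tep$amplitude)[[1]] <- ref_tep$subjects
template <- build_template(ref_tep)

feats <- delphi_features(pp$tep, template)
head(feats[, c("subject_id", "group", "hotspot", "epd", "lpd", "wfa", "stp")], 4)
#>   subject_id   group      hotspot    epd   lpd   wfa   stp
#> 1     sub001 healthy frontal_left -0.212 0.169 0.918 0.187
#> 2     sub002 healthy frontal_left -0.293 0.149 0.955 0.185
#> 3     sub003 healthy frontal_left -0.237 0.139 0.986 0.170
#> 4     sub004 healthy frontal_left -0.289 0.171 0.964 0.149

X <- build_feature_vector(feats)       # 16 features: 4 proximal hotspots x 4 measures
run_cv_svm(X, coh$labels[rownames(X)], seed = 1)
#> <cv_report> 50 permutations of stratified 5-fold CV (positive: injured)
#>   balanced_accuracy  0.955 +/- 0.016
#>   sensitivity        0.911 +/- 0.031
#>   specificity        0.999 +/- 0.007
#>   auc                0.984 +/- 0.009

run_cv_regression(X, coh$fa, seed = 1)
#> <regression_report> 13 ROIs, 40 subjects, 50 x 5-fold CV
#>   corpus_callosum_genu                       r 0.74 +/- 0.08  RMSE 0.047 +/- 0.011
#>   superior_longitudinal_fasciculus_L         r 0.61 +/- 0.17  RMSE 0.052 +/- 0.027
#>   superior_fronto_occipital_fasciculus_L     r 0.56 +/- 0.24  RMSE 0.054 +/- 0.034
#>   ...
```

Read: with a moderate simulated injury effect, the 16 proximal-hotspot
features classify injured vs healthy essentially perfectly (AUC 0.98),
and cross-validated FA prediction is strongest for the frontal/left
tracts given the highest severity loadings — the qualitative
proximity-to-stimulation-site gradient the measures are meant to show.
The numbers above are real package output (seeds as shown).

A full config-driven run (simulate → preprocess → features → stats →
classify → regress, with a manifest of MD5-checksummed outputs):

```r
rc <- run_config(sim = cfg, seed = 11)
run_pipeline(rc, "out_dir")
```

or from the shell, stage by stage:

```sh
Rscript -e 'tepnet::tepnet_cli()' run-all --config=cfg.json --out=out_dir
```

## Package layout

* `R/simulate.R`, `R/sim_config.R` — synthetic cohort generator.
* `R/preprocess.R`, `R/hotspots.R` — rejection, FIR, baseline, hotspots.
* `R/features.R` — EPD/LPD/WFA/MFP/STP, templates, feature vectors.
* `R/fa.R` — voxel-to-ROI FA summaries (FA > 0.2 mask).
* `R/group_stats.R` — pooled t-tests, Holm correction, comparison tables.
* `R/svm.R` + `src/svm_dcd.cpp` — linear SVM (dual coordinate descent).
* `R/cv_classify.R`, `R/cv_regress.R` — repeated stratified CV, mean ROC,
  per-ROI regression reports.
* `R/pipeline.R`, `R/io.R` — config, file-based stages, CLI, manifests.
* `vignettes/tepnet-methods.Rmd` — models, assumptions, calibration
  findings and limitations.
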