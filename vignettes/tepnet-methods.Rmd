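---
title: "TMS-evoked potentials as white-matter integrity biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMS-evoked potentials as white-matter integrity biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepnet)
```

## The problem

Transcranial magnetic stimulation with simultaneous EEG (TMS-EEG) probes
effective cortical connectivity: a magnetic pulse over motor cortex evokes a
stereotyped EEG deflection sequence — the TMS-evoked potential (TEP) — whose
shape, slopes and history-dependence reflect the integrity of the white-matter
(WM) networks that propagate the response. `tepnet` implements, end to end, an
analysis in which four scalar TEP measures per recording region serve as
biomarkers of WM damage: they discriminate injured from healthy cohorts with a
cross-validated linear SVM, and they predict per-tract mean fractional
anisotropy (FA, the DTI scalar in $[0,1]$ indexing WM microstructure) with a
cross-validated linear model. Because no suitable public cohort exists, the
package ships a first-class synthetic-cohort generator whose latent structure
makes every downstream stage testable.

## The four output measures

All measures are computed on hotspot-averaged TEPs restricted to the
20–300 ms post-stimulus window:

* **EPD** (early phase deflection): OLS slope of the single-pulse TEP over
  60–100 ms, in µV/ms.
* **LPD** (late phase deflection): OLS slope over 100–180 ms.
* **WFA** (waveform adherence): similarity of the full single-pulse TEP to a
  normative healthy template. Only a verbal definition exists upstream; it is
  operationalised here as the Pearson correlation over the full window,
  chosen for scale- and offset-invariance (cosine similarity is available via
  `wfa_metric = "cosine"`). Zero-variance waveforms yield `NA`, never a
  silent 0.
* **STP** (short-term plasticity index):
  $\mathrm{STP} = \frac{\mathrm{MFP}_{single} - \mathrm{MFP}_i}{\mathrm{MFP}_{single} + \mathrm{MFP}_i}$,
  where MFP (mean field potential) is operationalised as the mean rectified
  amplitude over 20–300 ms of the single-pulse and the 1 Hz
  inhibitory-protocol TEP respectively. A cross-electrode global-field-power
  MFP was rejected because it is incompatible with a per-hotspot STP. The
  index is antisymmetric and scale-invariant, positive when the inhibitory
  protocol suppresses the response.

Slopes are *signed*: deflection direction is informative and the measure is
linear in the waveform. EPD/LPD/WFA are computed on the single-pulse
condition only.

## Preprocessing

The documented stage order is **reject → filter → baseline → aggregate**:

1. *Epoch rejection*: an epoch is dropped per channel when its post-stimulus
   peak-to-peak amplitude exceeds 100 µV (the upstream methodology cites
   rejection of large artifacts without a number; 100 µV is a common TMS-EEG
   convention and is configurable). Rejection only flips retention flags, so
   `retained + rejected = recorded` holds exactly, and losing every epoch of
   a required electrode is a hard error.
2. *Bandpass*: 0.5–45 Hz zero-phase FIR. The kernel is a Hamming-windowed
   sinc with 6 dB cutoffs half a transition band outside the passband edges
   (0.5 Hz transition at the low edge, 5 Hz at the high edge); its symmetric,
   delay-compensated application has zero net phase so slope measures are
   not distorted. No DSP package in the supported environment provides this,
   so the design and FFT application are implemented in-package and verified
   by sinusoid probes (10 Hz preserved to within 0.2%, 60 Hz attenuated by
   more than 60 dB).
3. *Baseline*: per epoch/channel mean over −100…−10 ms subtracted (window
   configurable; the upstream text is silent, the window simply avoids
   pulse-adjacent samples).
4. *Hotspot aggregation*: epochs are averaged per electrode, electrodes
   averaged (unweighted) into eight regional hotspots, and the result cropped
   to 20–300 ms. The default map is frontal {F3,F5 | F4,F6}, parietal
   {C3,C5,CP1 | C4,C6,CP2}, temporal {CP5,CP3,FC5 | CP6,CP4,FC6} and
   occipital {O1,PO3 | O2,PO4}; "CF5", which appears in some listings, does
   not exist in the extended 10-20 system and is read as FC5.

## The synthetic cohort

`simulate_cohort()` generates a stated world, not a tuning surface:

* **TEP model**: a sum of five Gaussian-windowed components (P30, N45, P60,
  N100, P180 at 30/45/60/100/180 ms; amplitudes 4/−5/4.5/−8/3.5 µV) — the
  canonical motor-cortex TEP sequence. The source methodology never
  specifies waveform shape; this is a simulator convention and fully
  overridable.
* **Injury**: each injured subject carries one latent severity
  $s \in [0,1]$ (truncated normal) that (a) scales all component amplitudes
  by $\max(0, 1 - s\,w_h)$ with per-hotspot proximity weights $w_h$ (left
  temporal/parietal 1.0 down to right occipital 0.5, mimicking the greater
  sensitivity of regions proximal to a left-M1 stimulation site), (b) delays
  latencies by $20s$ ms, and (c) depresses FA linearly:
  $\mathrm{FA} = \mathrm{clip}(b_r - \ell_r s + \varepsilon,\ 0.05,\ 0.95)$
  with proximity-ordered loadings $\ell_r$. A single latent scalar couples
  EEG and FA so the regression stage has recoverable ground truth.
* **Plasticity**: the inhibitory-protocol response is scaled by 0.7 in a
  healthy network; injury flattens the contrast via
  $f(s) = 0.7 + 0.3\min(1, 0.5s)$, so STP shrinks with damage.
* **Noise**: AR(1) with coefficient 0.95 plus white noise, normalised to the
  configured marginal SD — cheap, seedable, spectrally plausible for EEG
  background. Artifact epochs (default 5%, 300 µV events applied across all
  electrodes) emulate movement/blink contamination.
* **Defaults**: 60 epochs/condition at 1 kHz over −100…350 ms (trial counts
  are unreported upstream; 60 is a realistic block), 20 hotspot electrodes,
  13 WM ROIs with healthy-adult baseline FA values.

What the generator does **not** emulate: volume conduction and field spread,
TMS pulse/decay artifacts, auditory-evoked contamination, age structure, or
spatially heterogeneous lesions (injury is a single scalar). A green test
therefore establishes that the *pipeline machinery* is correct and calibrated
— not that the measures would perform identically on real recordings.

## Evaluation protocols

**Classification.** The feature vector concatenates the four measures over
the four hotspots closest to the stimulation site (left/right temporal and
parietal): 16 values, hotspot-major, measure-minor. A linear SVM (L1 hinge,
dual coordinate descent — implemented in-package and verified against an
external solver during development; the fixed $C = 1$ is deliberately not
tuned) with inverse-class-frequency cost weighting — the interpretation used
for "class priors reflecting balanced proportions" — is evaluated under 50
permutations of stratified 5-fold CV. Features are z-scored with
training-fold statistics only; test-fold decision scores are pooled per
permutation; balanced accuracy, sensitivity and specificity are taken at the
zero threshold and the ROC is vertically averaged on a 101-point FPR grid
(the upstream "mean TPR against mean FPR" description is ambiguous between
threshold-wise and vertical averaging; vertical averaging is the
conventional choice). AUC is the trapezoid area of each permutation's own
curve, then mean ± SD.

**Regression.** Each ROI's mean FA is predicted from the same 16 features by
per-ROI OLS on the shared design (equivalent to multi-output linear
regression), under 50 × 5-fold CV with train-fold z-scoring; per permutation
the pooled test predictions give Pearson r and RMSE, aggregated as plain
mean ± SD (no Fisher-z). Rank-deficient training folds fall back to a small
fixed ridge penalty and are counted.

**Group statistics.** Per measure and hotspot, a pooled two-sample t-test
(equal-variance; the upstream text says only "two samples t-test"), with
Bonferroni–Holm correction applied within each measure panel of eight
hotspot cells (the panel is the most plausible correction family given
per-panel significance marks; a global family is available).

## Numerical and design choices

* FA ROI means use the strict mask FA > 0.2 ("higher than", not ≥); empty
  ROIs are flagged `NA` with `n_voxels_used = 0`.
* The normative WFA template is the pointwise mean single-pulse TEP of ≥ 5
  reference subjects whose ids are stored as provenance; evaluating any
  template donor is a hard error (leakage guard).
* Missing feature cells are imputed by the cohort median of the same
  (hotspot, measure) column with a log entry; subjects missing > 25% of
  cells are dropped.
* One global pipeline seed deterministically derives all stage seeds;
  identical config + seed reproduces every output file byte-for-byte, and
  the run manifest records MD5 checksums.
* Epoch containers serialise to delimited text plus a JSON metadata sidecar
  (the supported environment has no HDF5 R package; the layout is
  documented in `write_epoch_set()`).

## Calibration findings behind the acceptance tests

Two properties of repeated CV at desk scale shape how the acceptance tests
are phrased; both were measured with this package and cross-checked against
an independent implementation of the same protocol:

* *Dataset-level noise dominates.* For a null cohort of 40 + 40 subjects,
  the 50-permutation CV mean balanced accuracy is a property of the
  particular cohort draw with spread ≈ 0.06 (AUC ≈ 0.08) across cohorts —
  permutations share the data and cannot average it away. Calibration is
  therefore asserted on means over replicate cohorts (10–30, depending on
  the quantity), which are centred at chance as required.
* *CV correlation is attenuated at small n.* Even a *perfect* severity
  predictor placed among 15 noise features yields a cross-validated mean
  Pearson r of only ≈ 0.55 at n = 80 and ≈ 0.685 at n = 240 when the
  population value is $\sqrt{0.5} \approx 0.707$. Signal-recovery tests
  therefore run at n = 240 per cohort, where the attainable value sits
  inside the required band. In the strong-signal world the severity
  distribution (mean 0.4, SD 0.2) also stays below the saturation point at
  which a fully suppressed waveform stops encoding severity; with that,
  the features carry $R^2 \approx 0.997$ of the latent severity.

Acceptance cohorts are simulated at 250 Hz with 4–8 epochs per condition —
a pure runtime down-scaling of the 1 kHz / 60-epoch defaults — while CV
schemes stay at 50 × stratified 5-fold throughout.

## Known limitations

* The linear SVM uses a mildly regularised bias (augmented-feature
  formulation); with $C = 1$ and z-scored features the difference from an
  unregularised intercept is negligible.
* WFA templates are built per run from simulated reference subjects; no
  age-band-specific normative database is shipped.
* The FIR's 0.5 Hz low-edge transition implies a kernel longer than a
  single epoch; epochs are zero-padded, which is acceptable because the
  simulated TEP has no near-DC content, but real slow drifts would be
  handled better by filtering continuous recordings before epoching.
* BrainVision and NIfTI readers are out of scope; the package starts from
  arrays/tables (and its own text formats).
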