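Package: tepnet
Title: TMS-Evoked Potential Biomarkers of White-Matter Network Integrity
Version: 0.1.0
Authors@R: person("tepnet", "maintainers", email = "tepnet@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of transcranial magnetic stimulation
    evoked potentials (TEPs) as biomarkers of white-matter integrity.
    Generates synthetic TMS-EEG cohorts with linked diffusion-tensor
    fractional-anisotropy (FA) tables, preprocesses epoched EEG (artifact
    rejection, zero-phase FIR bandpass, baseline correction, regional hotspot
    averaging), extracts four electrophysiological measures (early/late phase
    deflection slopes, waveform adherence, short-term plasticity index), and
    evaluates them with repeated stratified cross-validation: linear-SVM
    classification of injured vs healthy with mean-ROC construction, and
    multivariate linear prediction of per-tract mean FA reported as Pearson r
    and RMSE. Includes univariate group comparisons with Bonferroni-Holm
    correction and a config-driven, fully seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
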