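#' Pipeline run configuration
#'
#' Bundles every stage's parameters. One global `seed` deterministically
#' derives per-stage seeds, so an identical config yields a byte-identical
#' report bundle. The configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]); output location is given
#' at run time, not stored in the config.
#'
#' @param sim a [sim_config()] for the main cohort.
#' @param n_reference healthy reference subjects simulated separately
#'   (distinct ids) to build the normative template without leakage.
#' @param reject_limit,filter_low,filter_high,baseline_window,tep_window
#'   preprocessing parameters, see [preprocess_epochs()].
#' @param wfa_metric,feature_hotspots feature options, see
#'   [compute_wfa()] and [build_feature_vector()].
#' @param cv list with `n_perm`, `k`, `C`, `class_weight`.
#' @param stats_family Holm correction family, see [compare_groups()].
#' @param seed global integer seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       n_reference = 10,
                       reject_limit = 100,
                       filter_low = 0.5, filter_high = 45,
                       baseline_window = c(-100, -10),
                       tep_window = c(20, 300),
                       wfa_metric = "pearson",
                       feature_hotspots = c("temporal_left", "temporal_right",
                                            "parietal_left", "parietal_right"),
                       cv = list(n_perm = 50, k = 5, C = 1,
                                 class_weight = "balanced"),
                       stats_family = "per_measure",
                       seed = 1L) {
  if (!inherits(sim, "sim_config")) {
    sim$component_params <- as.data.frame(sim$component_params,
                                          stringsAsFactors = FALSE)
    sim <- do.call(sim_config, sim)
  }
  cv <- modifyList(list(n_perm = 50, k = 5, C = 1, class_weight = "balanced"),
                   cv)
  stopifnot(n_reference >= 5, reject_limit > 0,
            length(baseline_window) == 2, length(tep_window) == 2,
            cv$n_perm >= 1, cv$k >= 2)
  structure(list(sim = sim, n_reference = as.integer(n_reference),
                 reject_limit = reject_limit,
                 filter_low = filter_low, filter_high = filter_high,
                 baseline_window = baseline_window, tep_window = tep_window,
                 wfa_metric = wfa_metric, feature_hotspots = feature_hotspots,
                 cv = cv, stats_family = stats_family,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # named atomic vectors must serialise as JSON objects, not bare arrays
  for (f in c("proximity_weights", "fa_baseline", "fa_loading"))
    x$sim[[f]] <- as.list(x$sim[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$sim <- as.list(x$sim)
  for (f in c("proximity_weights", "fa_baseline", "fa_loading"))
    x$sim[[f]] <- unlist(x$sim[[f]])
  x$sim$hotspot_map <- lapply(x$sim$hotspot_map, unlist)
  x$cv <- as.list(x$cv)
  do.call(run_config, x)
}

# deterministic per-stage seed derivation; stays below 2^31
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 9973) %% 2147483629 + 1)
}

rename_subjects <- function(cohort, prefix) {
  new <- paste0(prefix, cohort$epochs$subjects)
  es <- cohort$epochs
  es$subjects <- new
  names(es$groups) <- new
  dimnames(es$amplitude)[[1]] <- new
  dimnames(es$retained)[[1]] <- new
  cohort$epochs <- es
  cohort$fa$subject_id <- paste0(prefix, cohort$fa$subject_id)
  names(cohort$labels) <- new
  names(cohort$severity) <- new
  cohort
}

stage_path <- function(out_dir, file) file.path(out_dir, file)

#' Pipeline stages
#'
#' Each stage reads its inputs from and writes its outputs to `out_dir`
#' as plain files, so stages can be run (and unit-tested) independently;
#' [run_pipeline()] is exactly their composition. `stage_classify`
#' refuses (classed error `tepnet_single_class_error`) when only one group
#' is present; `run_pipeline` records that refusal and continues.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, the files written (or the stage's main object).
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_main <- config$sim; sim_main$seed <- derive_seed(config$seed, 1L)
  main <- simulate_cohort(sim_main)
  sim_ref <- config$sim
  sim_ref$n_healthy <- config$n_reference; sim_ref$n_injured <- 0L
  sim_ref$seed <- derive_seed(config$seed, 2L)
  ref <- rename_subjects(simulate_cohort(sim_ref), "ref_")
  write_epoch_set(main$epochs, stage_path(out_dir, "epochs_main"))
  write_epoch_set(ref$epochs, stage_path(out_dir, "epochs_ref"))
  write_table_tsv(main$fa, stage_path(out_dir, "fa.tsv"))
  write_table_tsv(
    data.frame(subject_id = names(main$labels), group = unname(main$labels),
               severity = unname(main$severity), stringsAsFactors = FALSE),
    stage_path(out_dir, "labels.tsv"))
  invisible(c("epochs_main", "epochs_ref", "fa.tsv", "labels.tsv"))
}

#' @rdname pipeline_stages
#' @export
stage_preprocess <- function(config, out_dir) {
  for (which in c("main", "ref")) {
    es <- read_epoch_set(stage_path(out_dir, paste0("epochs_", which)))
    pp <- preprocess_epochs(es, reject_limit = config$reject_limit,
                            low = config$filter_low, high = config$filter_high,
                            baseline_window = config$baseline_window,
                            map = config$sim$hotspot_map,
                            window = config$tep_window)
    write_table_tsv(tep_table(pp$tep),
                    stage_path(out_dir, paste0("teps_", which, ".tsv")))
    write_table_tsv(pp$rejection_log,
                    stage_path(out_dir, paste0("rejection_log_", which, ".tsv")))
  }
  invisible(c("teps_main.tsv", "teps_ref.tsv"))
}

#' @rdname pipeline_stages
#' @export
stage_features <- function(config, out_dir) {
  tep_main <- tep_from_table(read_table_tsv(stage_path(out_dir, "teps_main.tsv")))
  tep_ref <- tep_from_table(read_table_tsv(stage_path(out_dir, "teps_ref.tsv")))
  template <- build_template(tep_ref, age_band = "adult")
  feats <- delphi_features(tep_main, template, wfa_metric = config$wfa_metric)
  write_table_tsv(feats, stage_path(out_dir, "features.tsv"))
  write_template(template, stage_path(out_dir, "template"))
  invisible(c("features.tsv", "template.tsv"))
}

#' @rdname pipeline_stages
#' @export
stage_stats <- function(config, out_dir) {
  feats <- read_table_tsv(stage_path(out_dir, "features.tsv"))
  if (length(unique(feats$group)) == 2) {
    tab <- compare_groups(feats, family = config$stats_family)
  } else {
    message("group comparison skipped: single group present")
    tab <- data.frame(measure = character(), hotspot = character(),
                      mean_healthy = numeric(), se_healthy = numeric(),
                      mean_injured = numeric(), se_injured = numeric(),
                      t = numeric(), p = numeric(), p_adj = numeric(),
                      reject = logical(), stars = character(),
                      stringsAsFactors = FALSE)
  }
  write_table_tsv(tab, stage_path(out_dir, "comparison.tsv"))
  invisible("comparison.tsv")
}

#' @rdname pipeline_stages
#' @export
stage_classify <- function(config, out_dir) {
  feats <- read_table_tsv(stage_path(out_dir, "features.tsv"))
  if (length(unique(feats$group)) < 2)
    stop(structure(class = c("tepnet_single_class_error", "error", "condition"),
                   list(message = "classification refused: single class present",
                        call = NULL)))
  X <- build_feature_vector(feats, hotspots = config$feature_hotspots)
  labels <- read_table_tsv(stage_path(out_dir, "labels.tsv"))
  y <- labels$group[match(rownames(X), labels$subject_id)]
  rep <- run_cv_svm(X, y, n_perm = config$cv$n_perm, k = config$cv$k,
                    seed = derive_seed(config$seed, 3L), C = config$cv$C,
                    class_weight = config$cv$class_weight)
  jsonlite::write_json(
    list(summary = rep$summary, per_perm = rep$per_perm,
         settings = rep$settings),
    stage_path(out_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
  write_table_tsv(rep$roc, stage_path(out_dir, "roc.tsv"))
  invisible(rep)
}

#' @rdname pipeline_stages
#' @export
stage_regress <- function(config, out_dir) {
  feats <- read_table_tsv(stage_path(out_dir, "features.tsv"))
  X <- build_feature_vector(feats, hotspots = config$feature_hotspots)
  fa <- read_table_tsv(stage_path(out_dir, "fa.tsv"))
  rep <- run_cv_regression(X, fa, n_perm = config$cv$n_perm, k = config$cv$k,
                           seed = derive_seed(config$seed, 4L))
  write_table_tsv(rep$by_roi, stage_path(out_dir, "regression.tsv"))
  invisible(rep)
}

#' Run the full analysis pipeline
#'
#' Composition of the file-based stages: simulate, preprocess, features,
#' stats, classify, regress, then a run manifest (`manifest.json`) with
#' the config, derived stage seeds, record counts and MD5 checksums of
#' every output, so any bundle can be regenerated bit-identically from
#' its config and seed. A single-class cohort makes the classification
#' stage refuse; the refusal is recorded and the remaining stages
#' complete.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the manifest and the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, stage_path(out_dir, "config.json"))
  stage_simulate(config, out_dir)
  stage_preprocess(config, out_dir)
  stage_features(config, out_dir)
  stage_stats(config, out_dir)
  classification_refused <- FALSE
  tryCatch(stage_classify(config, out_dir),
           tepnet_single_class_error = function(e) {
             message(conditionMessage(e))
             classification_refused <<- TRUE
           })
  stage_regress(config, out_dir)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  md5 <- as.vector(tools::md5sum(file.path(out_dir, files)))
  feats <- read_table_tsv(stage_path(out_dir, "features.tsv"))
  manifest <- list(
    package = "tepnet",
    version = as.character(packageVersion("tepnet")),
    seed = config$seed,
    stage_seeds = list(simulate_main = derive_seed(config$seed, 1L),
                       simulate_ref = derive_seed(config$seed, 2L),
                       classify = derive_seed(config$seed, 3L),
                       regress = derive_seed(config$seed, 4L)),
    counts = list(subjects = length(unique(feats$subject_id)),
                  feature_rows = nrow(feats)),
    classification_refused = classification_refused,
    files = setNames(as.list(md5), files))
  jsonlite::write_json(manifest, stage_path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, out_dir = out_dir))
}

#' Command-line entry point
#'
#' `tepnet_cli(c("run-all", "--config=cfg.json", "--out=outdir"))` — the
#' subcommands `simulate`, `preprocess`, `features`, `stats`, `classify`,
#' `regress` and `run-all` each read the JSON config and operate on the
#' plain-file intermediates in the output directory, so any stage can be
#' re-run in isolation. `--seed=<int>` overrides the config's global seed.
#' An executable wrapper script is installed under
#' `system.file("exec", "tepnet", package = "tepnet")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return invisibly, the executed stage's return value.
#' @export
tepnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                 features = stage_features, stats = stage_stats,
                 classify = stage_classify, regress = stage_regress,
                 `run-all` = run_pipeline)
  usage <- paste0("usage: tepnet <", paste(names(stages), collapse = "|"),
                  "> --config=<json> [--out=<dir>] [--seed=<int>]")
  if (length(args) < 1 || !(args[1] %in% names(stages))) stop(usage)
  opt <- function(name, default = NULL) {
    hit <- grep(paste0("^--", name, "="), args, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^--", name, "="), "", hit[1])
  }
  cfg_path <- opt("config")
  if (is.null(cfg_path)) stop(usage)
  config <- read_run_config(cfg_path)
  seed <- opt("seed")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out_dir <- opt("out", "tepnet_out")
  invisible(stages[[args[1]]](config, out_dir))
}
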