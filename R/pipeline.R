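KNOWN_CONFIG_KEYS <- c("seed", "out_dir", "library_path", "fossil_path",
                       "simulate", "hdr_level", "alpha", "dataset_id",
                       "grid_nx", "grid_ny", "permutations", "shrinkage_d",
                       "min_measurements", "log_level")

#' Build and validate a pipeline configuration
#'
#' Either pass a named list or a YAML file path. Unknown keys are a
#' validation error (named in the message); referenced paths must resolve.
#'
#' @param config named list or path to a YAML config file.
#' @return validated \code{pipeline_config} list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, out_dir = tempfile("paleocolr_run_"),
                   library_path = NULL, fossil_path = NULL, simulate = TRUE,
                   hdr_level = 0.95, alpha = 0.05, dataset_id = 1L,
                   grid_nx = 151L, grid_ny = 151L, permutations = 999L,
                   shrinkage_d = 0.20, min_measurements = 5L,
                   log_level = "info")
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$hdr_level > 0, cfg$hdr_level < 1, cfg$alpha > 0,
            cfg$dataset_id %in% 1:6, cfg$shrinkage_d >= 0,
            cfg$shrinkage_d < 1, cfg$permutations >= 99)
  for (p in c(cfg$library_path, cfg$fossil_path))
    if (!is.null(p) && !file.exists(p)) stop("path not resolvable: ", p)
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end colour-inference pipeline
#'
#' Orders the full analysis: validate and filter measurements, compute
#' features, identify platelet samples, compute morphospace overlaps,
#' classify colours with self-test and leave-one-out validation, rerun
#' under the shrinkage scenario, and test anatomical autocorrelation with
#' a Mantel test. All stage outputs are written under the run directory as
#' delimited tables and JSON reports carrying the seed and parameter
#' digest; a rerun with the same config and seed is bit-identical.
#'
#' @param config \code{\link{pipeline_config}} (or list/path coercible to
#'   one).
#' @return invisibly, a list of all stage results plus \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  # inputs
  if (!is.null(config$library_path)) {
    library_raw <- read_measurements(config$library_path)
    fossil_raw <- read_measurements(config$fossil_path)
  } else {
    if (!isTRUE(config$simulate))
      stop("no input paths and simulate = FALSE")
    library_raw <- simulate_library(default_class_models(), seed = seed)
    fossil_raw <- simulate_slab(slab_config(seed = seed))
  }
  # stage 1: filter + features
  lib_v <- validate_and_filter(library_raw, config$min_measurements)
  fos_v <- validate_and_filter(fossil_raw, config$min_measurements)
  lib_meas <- lib_v$measurements
  fos_meas <- fos_v$measurements
  fos_feat <- compute_features(fos_meas,
                               min_measurements = config$min_measurements)
  write_measurements(fos_feat, file.path(config$out_dir,
                                         "fossil_features.tsv"))
  # stage 2: platelet identification against the non-platelet extant space
  reference <- hdr_reference(
    lib_meas[!grepl("platelet", lib_meas$colour_label), ],
    hdr_level = config$hdr_level)
  calls <- call_platelets(fos_meas, reference, hdr_level = config$hdr_level,
                          seed = derive_seed(seed, "platelet"))
  write_measurements(calls, file.path(config$out_dir, "platelet_calls.tsv"))
  # stage 3: morphospace overlap, fossil vs each extant class
  fossil_grouped <- fos_meas
  fossil_grouped$colour_label <- "fossil"
  pooled <- rbind(lib_meas[, names(fossil_grouped)], fossil_grouped)
  ov <- overlap_matrix(pooled, nx = config$grid_nx, ny = config$grid_ny)
  # stage 4: colour classification
  cls <- classify_colours(lib_meas, fos_meas,
                          training_config(config$dataset_id),
                          platelet_calls = calls, alpha = config$alpha,
                          min_measurements = config$min_measurements)
  write_measurements(cls$fossil_predictions,
                     file.path(config$out_dir, "colour_predictions.tsv"))
  # stage 5: shrinkage sensitivity
  sens <- sensitivity_report(
    lib_meas, fos_meas,
    scenarios = list(shrinkage_scenario(0),
                     shrinkage_scenario(config$shrinkage_d)),
    reference_points = reference,
    config = training_config(config$dataset_id),
    hdr_level = config$hdr_level, seed = derive_seed(seed, "sens"))
  # stage 6: anatomical autocorrelation
  mantel <- NULL
  if (!all(is.na(fos_feat$slab_x_mm))) {
    mantel <- mantel_test(morph_distance(fos_feat),
                          anatomical_distance(fos_feat),
                          n_permutations = config$permutations,
                          seed = derive_seed(seed, "mantel_stage"))
  }
  report <- list(
    filtering = list(library = lib_v[c("n_input", "n_retained")],
                     fossil = fos_v[c("n_input", "n_retained")],
                     fossil_exclusions = fos_v$log),
    platelet = list(n_platelet = sum(calls$verdict == "platelet"),
                    n_mixed = sum(calls$verdict == "mixed"),
                    calls = calls),
    overlap = list(fossil_vs = as.list(ov$overlap["fossil", ]),
                   bandwidth = ov$bandwidth),
    classification = list(
      retained_variables = cls$selection$retained,
      self_test_accuracy = cls$evaluation$self_test_accuracy,
      loo_accuracy = cls$evaluation$loo_accuracy,
      predictions = cls$fossil_predictions),
    sensitivity_changes = sens$changes,
    mantel = if (!is.null(mantel)) mantel[c("r", "p", "n_permutations")])
  write_report(report, file.path(config$out_dir, "report.json"),
               seed = seed, params = unclass(config)[
                 setdiff(KNOWN_CONFIG_KEYS, c("out_dir"))])
  invisible(list(config = config, filtering = list(library = lib_v,
                                                   fossil = fos_v),
                 features = fos_feat, platelet_calls = calls, overlap = ov,
                 classification = cls, sensitivity = sens, mantel = mantel,
                 out_dir = config$out_dir))
}
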