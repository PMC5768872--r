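#' Taphonomic shrinkage scenario
#'
#' Burial heat and pressure can shrink melanosome molds; the scenario
#' assumes both axes decreased by the fraction \code{d} and corrects fossil
#' measurements by the multiplicative factor \code{1/(1-d)} (0.20 gives
#' x1.25).
#'
#' @param d fractional decrease in both axes, in [0, 1).
#' @return a \code{shrinkage_scenario}.
#' @export
shrinkage_scenario <- function(d = 0.20) {
  if (d < 0 || d >= 1) stop("shrinkage fraction d must be in [0, 1)")
  structure(list(d = d, correction_factor = 1 / (1 - d)),
            class = "shrinkage_scenario")
}

#' Apply the shrinkage correction to fossil measurements
#'
#' Every length and diameter is multiplied by \code{1/(1-d)}. Because all
#' dimensionless features (CVs, skews, aspect ratio) are scale-invariant,
#' only \code{length_mean} and \code{diameter_mean} change downstream.
#'
#' @param measurements fossil measurement table.
#' @param scenario \code{\link{shrinkage_scenario}}.
#' @return corrected table; the scenario is recorded in the
#'   \code{shrinkage} attribute.
#' @export
apply_shrinkage_correction <- function(measurements,
                                       scenario = shrinkage_scenario()) {
  stopifnot(inherits(scenario, "shrinkage_scenario"))
  out <- measurements
  out$length_nm <- out$length_nm * scenario$correction_factor
  out$diameter_nm <- out$diameter_nm * scenario$correction_factor
  attr(out, "shrinkage") <- scenario
  out
}

#' Simulate shrinkage (the forward process)
#'
#' Multiplies both axes by \code{1-d}; the exact inverse of
#' \code{\link{apply_shrinkage_correction}}, used for round-trip checks.
#'
#' @inheritParams apply_shrinkage_correction
#' @export
simulate_shrinkage <- function(measurements, scenario = shrinkage_scenario()) {
  out <- measurements
  out$length_nm <- out$length_nm * (1 - scenario$d)
  out$diameter_nm <- out$diameter_nm * (1 - scenario$d)
  out
}

#' Shrinkage sensitivity report
#'
#' Reruns morphospace overlap, platelet identification and colour
#' classification under each shrinkage scenario and reports which
#' sample-level conclusions change relative to the first (baseline)
#' scenario.
#'
#' @param library_measurements labelled extant measurement table.
#' @param fossil_measurements fossil measurement table.
#' @param scenarios list of \code{\link{shrinkage_scenario}}s; the first is
#'   the baseline (typically d = 0).
#' @param reference_points reference non-platelet measurements for platelet
#'   calls.
#' @param config \code{\link{training_config}} used for classification.
#' @param hdr_level,seed forwarded to \code{\link{call_platelets}}.
#' @return list per scenario: overlaps of the fossil against each extant
#'   class, platelet verdicts, colour predictions; plus \code{changes},
#'   itemizing per-sample verdicts/predictions that differ from baseline.
#' @export
sensitivity_report <- function(library_measurements, fossil_measurements,
                               scenarios = list(shrinkage_scenario(0),
                                                shrinkage_scenario(0.20)),
                               reference_points = NULL,
                               config = training_config(1L),
                               hdr_level = 0.95, seed = 1L) {
  if (is.null(reference_points)) {
    non_platelet <- !grepl("platelet",
                           library_measurements$colour_label %||% "")
    reference_points <- library_measurements[non_platelet, , drop = FALSE]
  }
  reference_points <- hdr_reference(reference_points, hdr_level)
  run_one <- function(scn) {
    fossil <- apply_shrinkage_correction(fossil_measurements, scn)
    fossil$colour_label <- "fossil"
    pooled <- rbind(library_measurements[, names(fossil), drop = FALSE],
                    fossil)
    ov <- overlap_matrix(pooled)
    calls <- call_platelets(fossil, reference_points, hdr_level = hdr_level,
                            seed = seed)
    cls <- classify_colours(library_measurements, fossil, config,
                            platelet_calls = calls)
    list(scenario = scn, fossil_overlap = ov$overlap["fossil", ],
         platelet_calls = calls, predictions = cls$fossil_predictions)
  }
  results <- lapply(scenarios, run_one)
  names(results) <- vapply(scenarios, function(s) sprintf("d=%.2f", s$d), "")
  base <- results[[1]]
  changes <- lapply(results[-1], function(res) {
    verdict_changed <- base$platelet_calls$sample_id[
      base$platelet_calls$verdict != res$platelet_calls$verdict]
    m <- merge(base$predictions[, c("sample_id", "predicted_colour")],
               res$predictions[, c("sample_id", "predicted_colour")],
               by = "sample_id", suffixes = c("_base", "_scn"))
    pred_changed <- m$sample_id[m$predicted_colour_base !=
                                  m$predicted_colour_scn]
    list(platelet_verdict_changed = verdict_changed,
         prediction_changed = pred_changed)
  })
  list(results = results, changes = changes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
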