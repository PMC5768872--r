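#!/usr/bin/env Rscript
# Stage 6: taphonomic shrinkage sensitivity. Burial may have shrunk the
# fossil nanostructures; assuming a 20% decrease in both axes, fossil
# measurements are corrected by x1.25 and the overlap, platelet and colour
# analyses rerun. Dimensionless predictors are scale-invariant, so only
# size-driven conclusions can move.

suppressPackageStartupMessages(library(paleocolr))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

lib <- validate_and_filter(
  read_measurements("results/data/extant_library.tsv"))$measurements
slab <- validate_and_filter(
  read_measurements("results/data/fossil_slab.tsv"))$measurements

sens <- sensitivity_report(
  lib, slab,
  scenarios = list(shrinkage_scenario(0), shrinkage_scenario(0.20)),
  config = training_config(1), seed = seed)

for (nm in names(sens$results)) {
  cat(sprintf("\n== scenario %s ==\n", nm))
  cat("fossil overlaps:",
      paste(sprintf("%s=%.3f", names(sens$results[[nm]]$fossil_overlap),
                    sens$results[[nm]]$fossil_overlap), collapse = " "), "\n")
  print(table(sens$results[[nm]]$platelet_calls$verdict))
}
chg <- sens$changes[[1]]
cat(sprintf("\nconclusions changed by the 20%% scenario: %d platelet verdicts, %d colour predictions\n",
            length(chg$platelet_verdict_changed),
            length(chg$prediction_changed)))
write_report(list(platelet_verdict_changed = chg$platelet_verdict_changed,
                  prediction_changed = chg$prediction_changed),
             "results/shrinkage_sensitivity.json", seed = seed,
             params = list(d = 0.20))
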