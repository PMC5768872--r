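#!/usr/bin/env Rscript
# Stage 5: colour classification. Backward stepwise variable selection by
# partial Wilks' lambda (retain at p < 0.05), quadratic discriminant
# analysis with equal priors, self-test and leave-one-out validation, and
# fossil prediction under all six training-set configurations.

suppressPackageStartupMessages(library(paleocolr))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

lib <- validate_and_filter(
  read_measurements("results/data/extant_library.tsv"))$measurements
slab <- validate_and_filter(
  read_measurements("results/data/fossil_slab.tsv"))$measurements
reference <- hdr_reference(lib[!grepl("platelet", lib$colour_label), ])
calls <- call_platelets(slab, reference, seed = seed)

summaries <- lapply(1:6, function(id) {
  res <- classify_colours(lib, slab, training_config(id),
                          platelet_calls = calls)
  pred_tab <- table(res$fossil_predictions$predicted_colour)
  cat(sprintf("\n== training data set %d ==\n", id))
  cat("retained:", paste(res$selection$retained, collapse = ", "), "\n")
  cat(sprintf("self-test %.3f, leave-one-out %.3f (%d fossil samples)\n",
              res$evaluation$self_test_accuracy,
              res$evaluation$loo_accuracy,
              nrow(res$fossil_predictions)))
  print(pred_tab)
  if (id == 1L)
    write_measurements(res$fossil_predictions,
                       "results/colour_predictions.tsv")
  data.frame(dataset = id,
             retained = paste(res$selection$retained, collapse = ","),
             self_test = res$evaluation$self_test_accuracy,
             loo = res$evaluation$loo_accuracy,
             n_fossil = nrow(res$fossil_predictions))
})
write.table(do.call(rbind, summaries), "results/classification_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# body-region colour map under data set 1
pred <- read.delim("results/colour_predictions.tsv")
cat("\nbody-region colour map (data set 1):\n")
print(table(pred$body_region, pred$predicted_colour))
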