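#!/usr/bin/env Rscript
# Stage 1: generate the study data — an extant training library (seven
# colour classes with known melanosome morphology models) and a fossil
# slab of 53 sampling locations with a spatially correlated size field and
# a contiguous platelet-bearing patch.

suppressPackageStartupMessages(library(paleocolr))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

library_meas <- simulate_library(default_class_models(),
                                 n_samples_per_class = 20,
                                 n_meas_per_sample = 30, seed = seed)
slab <- simulate_slab(slab_config(seed = seed))
truth <- attr(slab, "truth")

write_measurements(library_meas, "results/data/extant_library.tsv")
write_measurements(slab, "results/data/fossil_slab.tsv")
write_measurements(truth, "results/data/fossil_slab_truth.tsv")

cat(sprintf("extant library: %d measurements, %d samples, %d classes\n",
            nrow(library_meas), length(unique(library_meas$sample_id)),
            length(unique(library_meas$colour_label))))
cat(sprintf("fossil slab: %d measurements, %d locations, %d platelet-bearing\n",
            nrow(slab), nrow(truth), sum(truth$is_platelet)))
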