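#!/usr/bin/env Rscript
# Stage 2: validate the raw tables (body-cavity exclusion, axis-order
# repair, minimum measurement counts) and compute the eight per-sample
# morphometric predictors.

suppressPackageStartupMessages(library(paleocolr))

lib_raw <- read_measurements("results/data/extant_library.tsv")
slab_raw <- read_measurements("results/data/fossil_slab.tsv")

lib_v <- validate_and_filter(lib_raw)
slab_v <- validate_and_filter(slab_raw)
cat(sprintf("library: %d of %d rows retained; slab: %d of %d\n",
            lib_v$n_retained, lib_v$n_input,
            slab_v$n_retained, slab_v$n_input))
if (nrow(slab_v$log) > 0) print(slab_v$log)

fossil_features <- compute_features(slab_v$measurements)
library_features <- compute_features(lib_v$measurements)
write_measurements(fossil_features, "results/fossil_features.tsv")
write_measurements(library_features, "results/library_features.tsv")
cat(sprintf("features: %d fossil locations x %d predictors\n",
            nrow(fossil_features), 8))
print(summary(fossil_features[, c("length_mean", "diameter_mean",
                                  "aspect_ratio_mean")]))
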