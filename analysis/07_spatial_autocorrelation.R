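#!/usr/bin/env Rscript
# Stage 7: anatomical autocorrelation. Are nanostructures in nearby slab
# regions statistically more similar than in distant regions? Mantel
# permutation test between the z-scored feature distance matrix and the
# slab-coordinate distance matrix (999 permutations, one-sided).

suppressPackageStartupMessages(library(paleocolr))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

features <- read.delim("results/fossil_features.tsv")
mt <- mantel_test(morph_distance(features),
                  anatomical_distance(features),
                  n_permutations = 999, seed = seed)
cat(sprintf("Mantel r = %.3f, one-sided p = %.3g (%d permutations, %d locations)\n",
            mt$r, mt$p, mt$n_permutations, nrow(features)))
write_report(list(r = mt$r, p = mt$p,
                  n_permutations = mt$n_permutations,
                  n_locations = nrow(features)),
             "results/mantel.json", seed = seed)
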