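#!/usr/bin/env Rscript
# Stage 4: kernel-density morphospace. One bandwidth (Silverman, per axis)
# estimated from the pooled measurements including the fossil; one shared
# 151x151 grid; proportional overlap = sum of pointwise minima of the
# proportion-normalized densities. Also: centroid-distance dispersion test
# and rarefaction of the (length, diameter) variance.

suppressPackageStartupMessages(library(paleocolr))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

lib <- validate_and_filter(
  read_measurements("results/data/extant_library.tsv"))$measurements
slab <- validate_and_filter(
  read_measurements("results/data/fossil_slab.tsv"))$measurements

slab$colour_label <- "fossil"
pooled <- rbind(lib[, names(slab)], slab)
ov <- overlap_matrix(pooled)
write.table(round(ov$overlap, 4), "results/overlap_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("bandwidth (nm):", round(ov$bandwidth, 1), "\n")
cat("fossil overlap with each extant class:\n")
print(round(sort(ov$overlap["fossil", ], decreasing = TRUE), 3))

cd <- centroid_distance_test(pooled)
cat(sprintf("centroid-distance dispersion: F = %.2f, p = %.3g\n",
            cd$F, cd$p))

rar <- rarefy_variance(slab[, c("length_nm", "diameter_nm")],
                       sizes = c(50, 100, 250, 500, 1000, nrow(slab)),
                       n_reps = 500, seed = seed)
write.table(rar, "results/rarefaction_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
flat <- abs(rar$mean[nrow(rar)] - rar$mean[nrow(rar) - 1]) /
  rar$mean[nrow(rar)]
cat(sprintf("rarefaction: last-step relative change %.3f%% (%s)\n",
            100 * flat,
            if (flat < 0.02) "sampling adequate" else "still rising"))
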