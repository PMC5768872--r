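#!/usr/bin/env Rscript
# Stage 3: two-criterion platelet identification. A fossil sample is
# platelet-bearing when (i) its measurements fall outside the 95%
# highest-density region of the non-platelet extant morphospace and
# (ii) its SEM images show stacking/moulding evidence; disagreements go to
# a 2-component Gaussian mixture that splits the sample's measurements.

suppressPackageStartupMessages(library(paleocolr))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

lib <- validate_and_filter(
  read_measurements("results/data/extant_library.tsv"))$measurements
slab <- validate_and_filter(
  read_measurements("results/data/fossil_slab.tsv"))$measurements
truth <- read.delim("results/data/fossil_slab_truth.tsv")

reference <- hdr_reference(lib[!grepl("platelet", lib$colour_label), ],
                           hdr_level = 0.95)
calls <- call_platelets(slab, reference, seed = seed)
write_measurements(calls, "results/platelet_calls.tsv")

print(table(calls$verdict))
m <- merge(calls, truth, by = "sample_id")
called <- m$verdict == "platelet"
cat(sprintf("sensitivity %.3f, specificity %.3f against generator truth\n",
            mean(called[m$is_platelet]), mean(!called[!m$is_platelet])))
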