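# shared fixture builders; everything is generated in code at test time

# minimal raw measurement table
raw_table <- function(sample_id, length_nm, diameter_nm, ...) {
  data.frame(sample_id = sample_id, length_nm = length_nm,
             diameter_nm = diameter_nm, ..., stringsAsFactors = FALSE)
}

# two classes with disjoint length supports: QDA must separate perfectly
separable_models <- function() {
  list(class_model("short_class", log(300), 0.05, log(150), 0.05),
       class_model("long_class", log(1500), 0.05, log(400), 0.05))
}

# small labelled library for classifier tests
tiny_library <- function(n_samples = 10L, n_meas = 20L, seed = 11L,
                         models = default_class_models()[
                           c("black", "brown", "iridescent",
                             "platelet_iridescence")]) {
  simulate_library(models, n_samples_per_class = n_samples,
                   n_meas_per_sample = n_meas, seed = seed)
}

# all length(p) permutations of 1..n (n small), for exhaustive Mantel
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# exhaustive-enumeration Mantel p-value (independent oracle): proportion of
# all n! relabelings with r_perm >= r_obs, identity included
mantel_p_exhaustive <- function(d1, d2) {
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  r_obs <- cor(v1, d2[lower])
  perms <- all_permutations(nrow(d1))
  r_all <- vapply(perms, function(idx) cor(v1, d2[idx, idx][lower]), 0)
  mean(r_all >= r_obs - 1e-12)
}

expect_binomial_ci <- function(observed_rate, p, n) {
  half <- 1.96 * sqrt(p * (1 - p) / n)
  expect_gte(observed_rate, p - half)
  expect_lte(observed_rate, p + half)
}
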