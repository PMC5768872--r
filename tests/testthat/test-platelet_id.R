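make_reference <- function(n = 600, seed = 31) {
  set.seed(seed)
  cbind(exp(rnorm(n, log(900), 0.2)), exp(rnorm(n, log(250), 0.2)))
}

test_that("HDR membership: points at the mode are inside, far points outside", {
  ref <- make_reference()
  at_mode <- ref[order(kde_eval(ref, ref, shared_bandwidth(ref)),
                       decreasing = TRUE)[1:10], ]
  res <- morphospace_exclusion(at_mode, ref)
  expect_false(res$outside)
  expect_equal(res$outside_fraction, 0)
  far <- ref * 10
  res_far <- morphospace_exclusion(far, ref)
  expect_true(res_far$outside)
  expect_equal(res_far$outside_fraction, 1)
  expect_error(morphospace_exclusion(at_mode, ref[1:20, ]), "at least 50")
})

test_that("expected outside fraction of reference-distributed points is 1 - hdr_level", {
  ref <- make_reference(n = 2000, seed = 32)
  set.seed(33)
  fresh <- cbind(exp(rnorm(2000, log(900), 0.2)),
                 exp(rnorm(2000, log(250), 0.2)))
  res <- morphospace_exclusion(fresh, ref, hdr_level = 0.95, majority = 0.5)
  expect_lt(abs(res$outside_fraction - 0.05), 0.02)
  res90 <- morphospace_exclusion(fresh, ref, hdr_level = 0.90)
  expect_lt(abs(res90$outside_fraction - 0.10), 0.025)
})

test_that("raising hdr_level never increases the outside fraction", {
  ref <- make_reference(n = 400, seed = 34)
  set.seed(35)
  sample_pts <- cbind(exp(rnorm(60, log(1200), 0.3)),
                      exp(rnorm(60, log(300), 0.3)))
  fracs <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(lvl)
    morphospace_exclusion(sample_pts, ref,
                          hdr_level = lvl)$outside_fraction, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("two-criterion rule: agreement cases need no clustering", {
  ref <- make_reference()
  inside <- data.frame(sample_id = "in", stacking_evidence = FALSE,
                       length_nm = ref[1:30, 1], diameter_nm = ref[1:30, 2])
  call_in <- call_platelet(inside, ref)
  expect_equal(call_in$verdict, "non_platelet")
  expect_false(any(call_in$platelet_flags))

  set.seed(36)
  platelet_pts <- cbind(exp(rnorm(30, log(3000), 0.1)),
                        exp(rnorm(30, log(1200), 0.1)))
  outside <- data.frame(sample_id = "out", stacking_evidence = TRUE,
                        length_nm = platelet_pts[, 1],
                        diameter_nm = platelet_pts[, 2])
  call_out <- call_platelet(outside, ref)
  expect_equal(call_out$verdict, "platelet")
  expect_true(all(call_out$platelet_flags))
  expect_true(call_out$criterion_i && call_out$criterion_ii)
})

test_that("disagreeing criteria trigger clustering that recovers sub-populations", {
  ref <- make_reference(n = 800, seed = 37)
  set.seed(38)
  n_each <- 40
  rod <- cbind(exp(rnorm(n_each, log(900), 0.15)),
               exp(rnorm(n_each, log(250), 0.15)))
  platelet <- cbind(exp(rnorm(n_each, log(3200), 0.12)),
                    exp(rnorm(n_each, log(1300), 0.12)))
  mixed <- data.frame(sample_id = "mix", stacking_evidence = TRUE,
                      length_nm = c(rod[, 1], platelet[, 1]),
                      diameter_nm = c(rod[, 2], platelet[, 2]))
  truth <- rep(c(FALSE, TRUE), each = n_each)
  res <- call_platelet(mixed, ref, seed = 4)
  expect_equal(res$verdict, "mixed")
  expect_gte(mean(res$platelet_flags == truth), 0.9)
})

test_that("partitioning removes exactly the platelet-flagged measurements", {
  ref <- make_reference()
  set.seed(39)
  meas <- data.frame(
    sample_id = rep(c("rod", "plate"), each = 20),
    stacking_evidence = rep(c(FALSE, TRUE), each = 20),
    length_nm = c(exp(rnorm(20, log(900), 0.1)),
                  exp(rnorm(20, log(3200), 0.1))),
    diameter_nm = c(exp(rnorm(20, log(250), 0.1)),
                    exp(rnorm(20, log(1300), 0.1))))
  calls <- call_platelets(meas, ref, seed = 2)
  parts <- partition_for_classification(calls, meas)
  expect_equal(nrow(parts$non_platelet) + nrow(parts$platelet), nrow(meas))
  expect_equal(unique(parts$non_platelet$sample_id), "rod")
  expect_equal(unique(parts$platelet$sample_id), "plate")
  # all-platelet input leaves an empty classifier stream with a warning
  plate_only <- meas[meas$sample_id == "plate", ]
  calls_p <- call_platelets(plate_only, ref, seed = 2)
  expect_warning(parts_p <- partition_for_classification(calls_p, plate_only),
                 "empty classifier stream")
  expect_equal(nrow(parts_p$non_platelet), 0L)
})

test_that("platelet calls on synthetic slabs recover the designated regions", {
  lib <- simulate_library(default_class_models()[
    c("black", "brown", "grey", "iridescent")], 8, 25, seed = 41)
  ref <- hdr_reference(lib)
  hits <- vapply(1:5, function(r) {
    slab <- simulate_slab(slab_config(n_locations = 24, n_platelet = 8,
                                      n_meas_per_location = 20,
                                      seed = 100 + r))
    truth <- attr(slab, "truth")
    calls <- call_platelets(slab, ref, seed = r)
    called <- calls$verdict[match(truth$sample_id, calls$sample_id)] ==
      "platelet"
    c(sens = mean(called[truth$is_platelet]),
      spec = mean(!called[!truth$is_platelet]))
  }, numeric(2))
  expect_gte(mean(hits["sens", ]), 0.9)
  expect_gte(mean(hits["spec", ]), 0.9)
})
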