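test_that("training configurations remap labels as specified", {
  labels <- c("black", "brown", "grey", "iridescent",
              "platelet_iridescence", "hummingbird_platelet",
              "penguin_brown_black")
  r1 <- paleocolr:::remap_labels(labels, training_config(1))
  expect_equal(r1[6], "platelet_iridescence")  # hummingbird pooled
  expect_equal(r1[7], "black")                 # penguin folded into black
  r2 <- paleocolr:::remap_labels(labels, training_config(2))
  expect_equal(r2[6], "hummingbird_platelet")  # hummingbird distinct
  expect_equal(r2[5], "platelet_iridescence")
  r3 <- paleocolr:::remap_labels(labels, training_config(3))
  expect_equal(r3[5], "iridescent")            # non-hummingbird platelets
  r5 <- paleocolr:::remap_labels(labels, training_config(5))
  expect_equal(r5[7], "penguin_brown_black")   # penguin distinct
  expect_error(training_config(7))
})

test_that("configuration 6 scales fossil size features by 1.25 only", {
  lib <- tiny_library(n_samples = 5, n_meas = 15, seed = 51)
  slab <- simulate_slab(slab_config(n_locations = 8, n_platelet = 0,
                                    n_meas_per_location = 15, seed = 51))
  ts1 <- build_training_set(lib, slab, training_config(1))
  ts6 <- build_training_set(lib, slab, training_config(6))
  expect_equal(ts6$fossil_features$length_mean,
               ts1$fossil_features$length_mean * 1.25, tolerance = 1e-12)
  expect_equal(ts6$fossil_features$diameter_mean,
               ts1$fossil_features$diameter_mean * 1.25, tolerance = 1e-12)
  for (v in c("length_cv", "diameter_cv", "aspect_ratio_mean",
              "aspect_ratio_skew", "length_skew", "diameter_skew"))
    expect_equal(ts6$fossil_features[[v]], ts1$fossil_features[[v]],
                 tolerance = 1e-12)
  expect_equal(ts6$features, ts1$features)  # training side untouched
})

test_that("configurations 4-5 classify only non-platelet fossil samples", {
  lib <- simulate_library(default_class_models(), 6, 20, seed = 52)
  slab <- simulate_slab(slab_config(n_locations = 16, n_platelet = 5,
                                    n_meas_per_location = 20, seed = 52))
  ref <- lib[!grepl("platelet", lib$colour_label), ]
  calls <- call_platelets(slab, ref, seed = 52)
  expect_error(build_training_set(lib, slab, training_config(4)),
               "requires platelet calls")
  ts4 <- build_training_set(lib, slab, training_config(4),
                            platelet_calls = calls)
  platelet_ids <- calls$sample_id[calls$verdict == "platelet"]
  expect_false(any(ts4$fossil_features$sample_id %in% platelet_ids))
})

test_that("stepwise selection drops noise, keeps signal, honours alpha", {
  set.seed(53)
  n <- 120
  g <- rep(c("a", "b", "c"), each = n / 3)
  informative <- rnorm(n) + c(a = -2, b = 0, c = 2)[g]
  noise <- rnorm(n)
  x <- cbind(informative = informative, noise = noise)
  sel <- stepwise_select(x, g)
  expect_true("informative" %in% sel$retained)
  expect_false("noise" %in% sel$retained)
  expect_equal(sel$trace$dropped, "noise")
  # alpha = 1 retains everything
  sel_all <- stepwise_select(x, g, alpha = 1)
  expect_setequal(sel_all$retained, c("informative", "noise"))
})

test_that("collinearity pre-pass removes duplicated variables before testing", {
  set.seed(54)
  n <- 90
  g <- rep(c("a", "b"), each = n / 2)
  v <- rnorm(n) + ifelse(g == "a", 0, 3)
  x <- cbind(v1 = v, v2 = v + rnorm(n, 0, 1e-6), w = rnorm(n))
  sel <- suppressWarnings(stepwise_select(x, g))
  expect_length(intersect(c("v1", "v2"), sel$dropped_collinear), 1L)
  expect_length(intersect(c("v1", "v2"), sel$retained), 1L)
})

test_that("QDA boundary for equal-variance 1D classes sits at the mean midpoint", {
  # closed form: with equal variances and priors the quadratic rule
  # reduces to the linear one, boundary (m1+m2)/2
  x <- matrix(c(-1, 0, 1, 3, 4, 5), ncol = 1,
              dimnames = list(NULL, "v"))
  labels <- rep(c("lo", "hi"), each = 3)
  model <- fit_qda(x, labels)
  score_gap <- function(t)
    diff(predict(model, matrix(t, 1, 1, dimnames = list(NULL, "v")))$scores[1, ])
  boundary <- uniroot(score_gap, c(0, 4), tol = 1e-12)$root
  expect_equal(boundary, 2, tolerance = 1e-9)
})

test_that("QDA is moment-sufficient and calibrated at class centres", {
  set.seed(55)
  x <- cbind(a = c(rnorm(30), rnorm(30, 8)), b = c(rnorm(30), rnorm(30, 8)))
  labels <- rep(c("p", "q"), each = 30)
  m1 <- fit_qda(x, labels)
  m2 <- fit_qda(rbind(x, x), rep(labels, 2))
  expect_equal(m1$params$p$mean, m2$params$p$mean)
  expect_equal(unname(m1$params$q$chol), unname(m2$params$q$chol),
               tolerance = 1e-6)
  at_mean <- matrix(m1$params$p$mean, 1, dimnames = list(NULL, c("a", "b")))
  expect_gt(predict(m1, at_mean)$posterior[, "p"], 0.99)
})

test_that("QDA posteriors match the independent MASS implementation", {
  skip_if_not_installed("MASS")
  set.seed(56)
  x <- cbind(a = c(rnorm(40, 0, 1), rnorm(40, 2, 2)),
             b = c(rnorm(40, 0, 2), rnorm(40, 1, 1)))
  labels <- rep(c("p", "q"), each = 40)
  ours <- fit_qda(x, labels, priors = "equal")
  ref <- MASS::qda(x, grouping = labels, prior = c(0.5, 0.5))
  new_x <- cbind(a = rnorm(25, 1), b = rnorm(25, 0.5))
  p_ours <- predict(ours, new_x)$posterior
  p_ref <- predict(ref, new_x)$posterior
  # MASS uses the n-1 covariance divisor where we use maximum likelihood,
  # so posteriors agree closely but not to machine precision
  expect_equal(unname(p_ours), unname(p_ref[, colnames(p_ours)]),
               tolerance = 0.05)
  expect_equal(predict(ours, new_x)$class,
               as.character(predict(ref, new_x)$class))
})

test_that("predictions are invariant under common affine feature rescaling", {
  set.seed(57)
  x <- cbind(a = c(rnorm(30), rnorm(30, 4)), b = c(rnorm(30), rnorm(30, 3)))
  labels <- rep(c("p", "q"), each = 30)
  test_x <- cbind(a = rnorm(20, 2), b = rnorm(20, 1.5))
  base <- predict(fit_qda(x, labels), test_x)$class
  resc <- function(m) sweep(sweep(m, 2, c(100, 0.01), "*"), 2, c(-5, 3), "+")
  rescaled <- predict(fit_qda(resc(x), labels), resc(test_x))$class
  expect_equal(rescaled, base)
})

test_that("separable classes give perfect self-test and LOO accuracy", {
  lib <- simulate_library(separable_models(), 8, 15, seed = 58)
  f <- compute_features(lib)
  ev <- evaluate_classifier(f, f$colour_label,
                            c("length_mean", "diameter_mean"))
  expect_equal(ev$self_test_accuracy, 1)
  expect_equal(ev$loo_accuracy, 1)
  expect_equal(sum(diag(ev$confusion)), 16)
})

test_that("LOO never exceeds chance systematically on label-free data", {
  set.seed(59)
  accs <- vapply(1:8, function(r) {
    x <- cbind(a = rnorm(40), b = rnorm(40))
    evaluate_classifier(x, rep(c("p", "q"), 20), c("a", "b"))$loo_accuracy
  }, 0)
  expect_binomial_ci(mean(accs), 0.5, 8 * 40)
})

test_that("fossil prediction reports full posteriors and checks variables", {
  lib <- simulate_library(separable_models(), 6, 15, seed = 60)
  f <- compute_features(lib)
  model <- fit_qda(f, f$colour_label, variables = c("length_mean",
                                                    "diameter_mean"))
  preds <- predict_fossil(model, f[1:4, ])
  post <- as.matrix(preds[, grep("^post_", names(preds))])
  expect_equal(unname(rowSums(post)), rep(1, 4), tolerance = 1e-12)
  expect_equal(preds$predicted_colour, f$colour_label[1:4])
  f_missing <- f[, setdiff(names(f), "diameter_mean")]
  expect_error(predict_fossil(model, f_missing), "diameter_mean")
})
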