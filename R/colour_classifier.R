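#' Wilks' lambda for group discrimination
#'
#' Ratio of the within-group to total sum-of-squares-and-cross-products
#' determinants; small values mean strong discrimination.
#'
#' @param x numeric matrix (observations x variables).
#' @param groups factor of group labels.
#' @return scalar lambda in (0, 1].
#' @export
wilks_lambda <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  tot <- crossprod(scale(x, center = TRUE, scale = FALSE))
  within <- Reduce(`+`, lapply(split(as.data.frame(x), groups), function(d)
    crossprod(scale(as.matrix(d), center = TRUE, scale = FALSE))))
  det(within) / det(tot)
}

# partial Wilks F-test for one variable given the others:
# lambda_partial = lambda(all) / lambda(all minus j), transformed to an
# F(g-1, n-g-p+1) statistic (standard stepwise discriminant analysis)
partial_wilks_test <- function(x, groups, j) {
  n <- nrow(x)
  g <- nlevels(factor(groups))
  p <- ncol(x)
  lam_full <- wilks_lambda(x, groups)
  lam_red <- if (p == 1L) 1 else wilks_lambda(x[, -j, drop = FALSE], groups)
  lam_p <- lam_full / lam_red
  df2 <- n - g - p + 1
  if (df2 <= 0) stop("too few observations for a partial Wilks test")
  F <- (df2 / (g - 1)) * (1 - lam_p) / lam_p
  p_val <- pf(F, g - 1, df2, lower.tail = FALSE)
  c(F = F, p = p_val, lambda_partial = lam_p)
}

#' Backward stepwise variable selection by partial Wilks' lambda
#'
#' Starting from all candidate predictors, repeatedly drops the variable
#' with the largest partial-test p-value exceeding \code{alpha} (partial
#' Wilks' lambda F comparing the model with and without the variable) until
#' every retained variable is significant. A multicollinearity pre-pass
#' first drops the weaker member (larger univariate p) of any variable pair
#' correlated beyond \code{collinearity_r}, preventing singular within-class
#' covariances downstream.
#'
#' @param features numeric matrix or feature data.frame.
#' @param labels class labels.
#' @param alpha retention threshold (default 0.05).
#' @param collinearity_r absolute-correlation threshold for the pre-pass.
#' @return list: \code{retained} variable names, \code{dropped_collinear},
#'   \code{trace} data.frame logging each elimination.
#' @export
stepwise_select <- function(features, labels, alpha = 0.05,
                            collinearity_r = 0.95) {
  x <- if (is.data.frame(features)) feature_matrix(features,
    intersect(FEATURE_NAMES, names(features))) else as.matrix(features)
  groups <- factor(labels)
  stopifnot(nlevels(groups) >= 2L, nrow(x) == length(labels))
  if (any(table(groups) <= ncol(x)))
    warning("some classes have no more samples than candidate variables")
  uni_p <- vapply(seq_len(ncol(x)), function(j)
    anova(lm(x[, j] ~ groups))[1, "Pr(>F)"], 0)
  names(uni_p) <- colnames(x)
  # collinearity pre-pass: drop weaker member of any |r| > threshold pair
  dropped_collinear <- character(0)
  keep <- colnames(x)
  repeat {
    cm <- abs(cor(x[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (all(cm <= collinearity_r, na.rm = TRUE)) break
    pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    members <- keep[pair]
    weaker <- members[which.max(uni_p[members])]
    dropped_collinear <- c(dropped_collinear, weaker)
    keep <- setdiff(keep, weaker)
  }
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(keep) == 0L)
      stop("all variables eliminated; trace: ",
           paste(trace$dropped, collapse = " > "))
    tests <- t(vapply(seq_along(keep), function(j)
      partial_wilks_test(x[, keep, drop = FALSE], groups, j), numeric(3)))
    rownames(tests) <- keep
    worst <- which.max(tests[, "p"])
    if (tests[worst, "p"] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = keep[worst],
                                     p = tests[worst, "p"]))
    keep <- keep[-worst]
  }
  list(retained = keep, dropped_collinear = dropped_collinear, trace = trace,
       alpha = alpha)
}

#' Fit a quadratic discriminant model
#'
#' Per-class Gaussian maximum-likelihood estimates on the retained
#' variables; the discriminant score is
#' \code{delta_k(x) = -log|Sigma_k|/2 - (x-mu_k)' Sigma_k^{-1} (x-mu_k)/2 +
#' log pi_k} and posteriors are proportional to \code{exp(delta_k)}.
#' Covariances are maximum-likelihood (divisor n) estimates with a relative
#' ridge of 1e-8 on each diagonal element before inversion, keeping
#' predictions exactly invariant under per-feature affine rescaling applied
#' identically to training and test data.
#'
#' @param features matrix or feature data.frame (retained variables only).
#' @param labels class labels.
#' @param priors \code{"equal"} (default: fossil class frequencies are
#'   unknowable), \code{"frequency"}, or a named numeric vector summing
#'   to 1.
#' @param variables optional subset of columns to use.
#' @return a \code{qda_model}.
#' @export
fit_qda <- function(features, labels, priors = "equal", variables = NULL) {
  x <- if (is.data.frame(features)) feature_matrix(features,
    if (is.null(variables)) intersect(FEATURE_NAMES, names(features)) else
      variables) else {
        m <- as.matrix(features)
        if (!is.null(variables)) m[, variables, drop = FALSE] else m
      }
  groups <- factor(labels)
  classes <- levels(groups)
  p <- ncol(x)
  if (is.character(priors)) {
    pri <- switch(match.arg(priors, c("equal", "frequency")),
                  equal = rep(1 / length(classes), length(classes)),
                  frequency = as.numeric(table(groups)) / length(groups))
    names(pri) <- classes
  } else {
    stopifnot(abs(sum(priors) - 1) < 1e-8, all(classes %in% names(priors)))
    pri <- priors[classes]
  }
  params <- lapply(classes, function(cl) {
    xc <- x[groups == cl, , drop = FALSE]
    if (nrow(xc) < 2L) stop("class ", cl, " has fewer than 2 samples")
    # ML covariance (divisor n), so duplicating training rows is a no-op;
    # ridge proportional to each variable's own variance keeps the model
    # exactly equivariant under per-feature affine rescaling
    S <- cov(xc) * (nrow(xc) - 1) / nrow(xc)
    S <- S + diag(1e-8 * pmax(diag(S), 1e-300), p)
    ch <- tryCatch(chol(S), error = function(e)
      stop("singular covariance for class ", cl))
    list(mean = colMeans(xc), chol = ch,
         log_det = 2 * sum(log(diag(ch))), n = nrow(xc))
  })
  names(params) <- classes
  structure(list(classes = classes, variables = colnames(x),
                 params = params, priors = pri),
            class = "qda_model")
}

#' Predict classes and posteriors from a fitted QDA
#'
#' @param object \code{qda_model}.
#' @param newdata matrix or feature data.frame containing the model's
#'   retained variables.
#' @param ... unused.
#' @return list: \code{class} (character), \code{posterior} (matrix, rows
#'   sum to 1), \code{scores} (discriminant scores).
#' @export
predict.qda_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    miss <- setdiff(object$variables, names(newdata))
    if (length(miss) > 0L)
      stop("missing retained variable(s): ", paste(miss, collapse = ", "))
    feature_matrix(newdata, object$variables)
  } else {
    m <- as.matrix(newdata)
    if (!is.null(colnames(m))) {
      miss <- setdiff(object$variables, colnames(m))
      if (length(miss) > 0L)
        stop("missing retained variable(s): ", paste(miss, collapse = ", "))
      m <- m[, object$variables, drop = FALSE]
    }
    m
  }
  scores <- vapply(object$classes, function(cl) {
    pp <- object$params[[cl]]
    z <- backsolve(pp$chol, t(x) - pp$mean, transpose = TRUE)
    -0.5 * pp$log_det - 0.5 * colSums(z^2) + log(object$priors[[cl]])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(rownames(x), object$classes))
  m <- apply(scores, 1L, max)
  post <- exp(scores - m)
  post <- post / rowSums(post)
  list(class = object$classes[max.col(post, ties.method = "first")],
       posterior = post, scores = scores)
}

#' Self-test and leave-one-out evaluation
#'
#' Self-test is resubstitution accuracy of the model fitted on all samples;
#' leave-one-out cross-validation refits the QDA once per held-out sample
#' with the variable set fixed from the full-data selection. Folds whose
#' training split empties a class are skipped with a warning and counted.
#'
#' @param features feature data.frame or matrix.
#' @param labels class labels.
#' @param variables retained variables.
#' @param priors see \code{\link{fit_qda}}.
#' @return list: \code{self_test_accuracy}, \code{loo_accuracy},
#'   \code{confusion} (LOO confusion matrix), \code{n_skipped_folds},
#'   \code{model} (full-data fit).
#' @export
evaluate_classifier <- function(features, labels, variables,
                                priors = "equal") {
  groups <- factor(labels)
  model <- fit_qda(features, labels, priors = priors, variables = variables)
  self_pred <- predict(model, features)$class
  n <- length(labels)
  loo_pred <- rep(NA_character_, n)
  skipped <- 0L
  idx_df <- is.data.frame(features)
  for (i in seq_len(n)) {
    tr_lab <- groups[-i]
    if (any(table(droplevels(tr_lab)) < 2L) ||
        nlevels(droplevels(tr_lab)) < nlevels(groups)) {
      skipped <- skipped + 1L
      next
    }
    tr <- if (idx_df) features[-i, , drop = FALSE] else
      features[-i, , drop = FALSE]
    m_i <- fit_qda(tr, as.character(tr_lab), priors = priors,
                   variables = variables)
    te <- if (idx_df) features[i, , drop = FALSE] else
      features[i, , drop = FALSE]
    loo_pred[i] <- predict(m_i, te)$class
  }
  if (skipped > 0L)
    warning(skipped, " leave-one-out fold(s) skipped (class would empty)")
  ok <- !is.na(loo_pred)
  confusion <- table(truth = groups[ok],
                     predicted = factor(loo_pred[ok], levels = levels(groups)))
  list(self_test_accuracy = mean(self_pred == as.character(groups)),
       loo_accuracy = mean(loo_pred[ok] == as.character(groups)[ok]),
       confusion = confusion, n_skipped_folds = skipped, model = model)
}

#' Training-set configuration
#'
#' The six training configurations differ in class scheme, in whether the
#' fossil measurements receive the taphonomic shrinkage correction, and in
#' whether platelet-bearing fossil samples are classified: (1) black,
#' brown, grey, iridescent plus a pooled platelet-iridescence class;
#' (2) as 1 with hummingbird platelets distinct; (3) hummingbird platelets
#' distinct and non-hummingbird platelets merged into rod iridescence;
#' (4) as 1 but classifying only non-platelet fossil samples; (5) as 4 with
#' penguin brown-black as its own class; (6) as 1 with a 20% shrinkage
#' correction applied to the fossil.
#'
#' @param dataset_id integer 1-6.
#' @return a \code{training_config}.
#' @export
training_config <- function(dataset_id) {
  dataset_id <- as.integer(dataset_id)
  stopifnot(dataset_id %in% 1:6)
  structure(list(
    dataset_id = dataset_id,
    shrinkage = dataset_id == 6L,
    shrinkage_d = if (dataset_id == 6L) 0.20 else 0,
    non_platelet_only = dataset_id %in% 4:5,
    penguin_distinct = dataset_id == 5L),
    class = "training_config")
}

# label remapping per configuration; base labels are the seven-class scheme
remap_labels <- function(labels, config) {
  out <- as.character(labels)
  if (config$dataset_id %in% c(1L, 4L, 6L) ||
      (config$dataset_id == 5L && !config$penguin_distinct)) {
    out[out == "hummingbird_platelet"] <- "platelet_iridescence"
  }
  if (config$dataset_id == 2L) {
    # hummingbird platelets distinct; other platelets pooled
  }
  if (config$dataset_id == 3L) {
    out[out == "platelet_iridescence"] <- "iridescent"
  }
  if (config$dataset_id == 5L) {
    out[out == "hummingbird_platelet"] <- "platelet_iridescence"
  } else {
    out[out == "penguin_brown_black"] <- "black"
  }
  out
}

#' Assemble a training set and fossil prediction set
#'
#' Applies the configuration's class scheme to the extant library, applies
#' the shrinkage correction to fossil measurements for configuration 6, and
#' restricts the fossil prediction set to non-platelet samples for
#' configurations 4-5 (platelet calls required in that case).
#'
#' @param library_measurements labelled extant measurement table.
#' @param fossil_measurements fossil measurement table.
#' @param config \code{\link{training_config}}.
#' @param platelet_calls output of \code{\link{call_platelets}} on the
#'   fossil; required for configurations 4-6 (4-5 drop platelet samples,
#'   6 keeps them but corrects sizes).
#' @param min_measurements forwarded to \code{\link{compute_features}}.
#' @return list: \code{features} (training), \code{labels},
#'   \code{fossil_features}, \code{config}.
#' @export
build_training_set <- function(library_measurements, fossil_measurements,
                               config, platelet_calls = NULL,
                               min_measurements = 5L) {
  stopifnot(inherits(config, "training_config"))
  lib_feat <- compute_features(library_measurements,
                               min_measurements = min_measurements)
  labels <- remap_labels(lib_feat$colour_label, config)
  small <- names(which(table(labels) < 3L))
  if (length(small) > 0L)
    stop("configured class(es) with fewer than 3 training samples: ",
         paste(small, collapse = ", "))
  fossil <- fossil_measurements
  if (config$non_platelet_only) {
    if (is.null(platelet_calls))
      stop("configuration ", config$dataset_id, " requires platelet calls")
    fossil <- partition_for_classification(platelet_calls,
                                           fossil)$non_platelet
  }
  if (config$shrinkage)
    fossil <- apply_shrinkage_correction(fossil,
      shrinkage_scenario(config$shrinkage_d))
  fossil_feat <- compute_features(fossil, min_measurements = min_measurements)
  list(features = lib_feat, labels = labels, fossil_features = fossil_feat,
       config = config)
}

#' Predict fossil sample colours
#'
#' Arg-max posterior class per fossil sample with the full posterior
#' vector; a body-region colour map is assembled from sample metadata when
#' present.
#'
#' @param model fitted \code{qda_model}.
#' @param fossil_features fossil feature data.frame (must contain the
#'   model's retained variables).
#' @return data.frame: sample_id, body_region (if present), predicted
#'   class, posterior columns.
#' @export
predict_fossil <- function(model, fossil_features) {
  pred <- predict(model, fossil_features)
  out <- data.frame(sample_id = fossil_features$sample_id,
                    stringsAsFactors = FALSE)
  if ("body_region" %in% names(fossil_features))
    out$body_region <- fossil_features$body_region
  out$predicted_colour <- pred$class
  post <- as.data.frame(pred$posterior)
  names(post) <- paste0("post_", names(post))
  cbind(out, post)
}

#' Run one full colour-classification analysis
#'
#' Variable selection on the training set, QDA fit, self-test and
#' leave-one-out validation, and fossil prediction, for one training
#' configuration.
#'
#' @inheritParams build_training_set
#' @param alpha stepwise retention threshold.
#' @param priors see \code{\link{fit_qda}}.
#' @return list: \code{selection}, \code{evaluation}, \code{fossil_predictions},
#'   \code{config}.
#' @export
classify_colours <- function(library_measurements, fossil_measurements,
                             config = training_config(1L),
                             platelet_calls = NULL, alpha = 0.05,
                             priors = "equal", min_measurements = 5L) {
  ts <- build_training_set(library_measurements, fossil_measurements, config,
                           platelet_calls = platelet_calls,
                           min_measurements = min_measurements)
  sel <- stepwise_select(ts$features, ts$labels, alpha = alpha)
  ev <- evaluate_classifier(ts$features, ts$labels, sel$retained,
                            priors = priors)
  preds <- if (nrow(ts$fossil_features) > 0L)
    predict_fossil(ev$model, ts$fossil_features) else NULL
  list(selection = sel, evaluation = ev, fossil_predictions = preds,
       config = config)
}
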