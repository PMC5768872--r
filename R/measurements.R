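#' @importFrom stats sd var cov cor quantile dnorm qnorm pnorm pf rnorm runif
#'   aov anova lm complete.cases setNames aggregate dist cutree hclust
#' @importFrom utils read.delim write.table head
NULL

MANDATORY_COLS <- c("sample_id", "length_nm", "diameter_nm")

OPTIONAL_COLS <- c("taxon", "source", "body_region", "slab_x_mm", "slab_y_mm",
                   "colour_label", "near_body_cavity", "stacking_evidence",
                   "measurement_id")

FEATURE_NAMES <- c("length_mean", "length_cv", "diameter_mean", "diameter_cv",
                   "aspect_ratio_mean", "aspect_ratio_skew", "length_skew",
                   "diameter_skew")

#' Moment (Fisher-Pearson) skewness
#'
#' Standardized third central moment without small-sample bias correction
#' (the "type 1" / moment estimator). Returns 0 with a warning when the
#' variance is degenerate, so downstream feature vectors stay finite.
#'
#' @param x numeric vector, length >= 2.
#' @return scalar skewness.
#' @export
skewness_moment <- function(x) {
  n <- length(x)
  if (n < 2L) stop("skewness requires at least 2 values")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) {
    warning("degenerate variance: skewness set to 0")
    return(0)
  }
  mean((x - m)^3) / s2^1.5
}

#' Validate and filter a nanostructure measurement table
#'
#' Applies the pre-analysis filtering rules to a raw measurement table:
#' measurements flagged as taken near the body cavity are dropped, rows with
#' non-positive length or diameter are rejected, rows whose length is smaller
#' than their diameter have the two axes swapped (axis assignment in manual
#' image measurement is error-prone, so a swap with a warning is preferred to
#' rejection), and samples left with fewer than \code{min_measurements}
#' measurements are excluded from feature computation. Every exclusion is
#' itemized in the returned log.
#'
#' @param raw data.frame with at least \code{sample_id}, \code{length_nm},
#'   \code{diameter_nm}; optional metadata columns \code{taxon},
#'   \code{source}, \code{body_region}, \code{slab_x_mm}, \code{slab_y_mm},
#'   \code{colour_label}, \code{near_body_cavity}, \code{stacking_evidence},
#'   \code{measurement_id}.
#' @param min_measurements minimum number of retained measurements a sample
#'   needs to enter feature computation (default 5).
#' @return list with \code{measurements} (the retained rows), \code{log}
#'   (data.frame itemizing every excluded row or sample with a reason),
#'   \code{n_input}, \code{n_retained}, and \code{small_samples} (sample ids
#'   excluded for having too few measurements).
#' @export
validate_and_filter <- function(raw, min_measurements = 5L) {
  stopifnot(is.data.frame(raw))
  missing_cols <- setdiff(MANDATORY_COLS, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  log_entries <- list()
  note <- function(ids, reason) {
    if (length(ids) > 0L)
      log_entries[[length(log_entries) + 1L]] <<-
        data.frame(sample_id = as.character(ids), reason = reason,
                   stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(list(measurements = raw, log = empty_log(), n_input = 0L,
                n_retained = 0L, small_samples = character(0)))
  }
  if ("measurement_id" %in% names(raw)) {
    key <- paste(raw$sample_id, raw$measurement_id, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (sample_id, measurement_id) pair(s): ",
           paste(unique(raw$sample_id[duplicated(key)]), collapse = ", "))
  }
  x <- raw
  # body-cavity exclusion precedes all analyses
  if ("near_body_cavity" %in% names(x)) {
    nbc <- as_logical_col(x$near_body_cavity)
    note(x$sample_id[nbc %in% TRUE], "near_body_cavity")
    x <- x[!(nbc %in% TRUE), , drop = FALSE]
  }
  bad <- !is.finite(x$length_nm) | !is.finite(x$diameter_nm) |
    x$length_nm <= 0 | x$diameter_nm <= 0
  note(x$sample_id[bad], "non_positive_or_missing_value")
  x <- x[!bad, , drop = FALSE]
  swap <- x$length_nm < x$diameter_nm
  if (any(swap)) {
    warning(sum(swap), " row(s) had length < diameter; axes swapped")
    tmp <- x$length_nm[swap]
    x$length_nm[swap] <- x$diameter_nm[swap]
    x$diameter_nm[swap] <- tmp
  }
  counts <- table(x$sample_id)
  small <- names(counts)[counts < min_measurements]
  note(small, sprintf("fewer_than_%d_measurements", min_measurements))
  x <- x[!(x$sample_id %in% small), , drop = FALSE]
  rownames(x) <- NULL
  log_df <- if (length(log_entries)) do.call(rbind, log_entries) else empty_log()
  list(measurements = x, log = log_df, n_input = nrow(raw),
       n_retained = nrow(x), small_samples = small)
}

empty_log <- function() {
  data.frame(sample_id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

as_logical_col <- function(v) {
  if (is.logical(v)) return(v)
  out <- rep(NA, length(v))
  s <- tolower(trimws(as.character(v)))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Per-sample morphometric feature vectors
#'
#' Computes, for each sample (or other grouping unit), the eight candidate
#' colour predictors: mean length, length CV, mean diameter, diameter CV,
#' mean aspect ratio, aspect-ratio skew, length skew and diameter skew.
#' Means are arithmetic; CV is the n-1 sample standard deviation divided by
#' the mean; the aspect ratio is computed per measurement as length/diameter
#' and then averaged; skewness is the moment (Fisher-Pearson) estimator.
#' All dimensionless features are exactly invariant under a common rescaling
#' of both axes.
#'
#' @param measurements validated measurement table (see
#'   \code{\link{validate_and_filter}}).
#' @param group_by column name defining the feature unit; default
#'   \code{"sample_id"}. Extant libraries may be pooled per taxon by passing
#'   \code{"taxon"}.
#' @param min_measurements groups below this size are dropped with a warning.
#' @return data.frame, one row per group: the grouping key, the eight
#'   features, \code{n_measurements}, and carried-through metadata columns
#'   that are constant within the group.
#' @export
compute_features <- function(measurements, group_by = "sample_id",
                             min_measurements = 5L) {
  stopifnot(is.data.frame(measurements), group_by %in% names(measurements))
  if (nrow(measurements) == 0L)
    return(cbind(data.frame(sample_id = character(0)),
                 as.data.frame(matrix(numeric(0), 0, length(FEATURE_NAMES),
                                      dimnames = list(NULL, FEATURE_NAMES))),
                 n_measurements = integer(0)))
  groups <- split(measurements, measurements[[group_by]], drop = TRUE)
  small <- names(groups)[vapply(groups, nrow, 0L) < min_measurements]
  if (length(small) > 0L) {
    warning("dropping group(s) with fewer than ", min_measurements,
            " measurements: ", paste(small, collapse = ", "))
    groups <- groups[!(names(groups) %in% small)]
  }
  meta_cols <- intersect(c("taxon", "source", "body_region", "slab_x_mm",
                           "slab_y_mm", "colour_label", "stacking_evidence"),
                         names(measurements))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    fv <- feature_vector(d$length_nm, d$diameter_nm)
    row <- data.frame(g, t(fv), n_measurements = nrow(d),
                      stringsAsFactors = FALSE)
    names(row)[1] <- group_by
    for (mc in meta_cols) {
      u <- unique(d[[mc]])
      row[[mc]] <- if (length(u) == 1L) u else NA
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "feature_meta") <- list(skewness = "moment (type 1)",
                                    aspect_ratio = "mean of per-measurement ratios",
                                    cv = "sd(n-1)/mean",
                                    group_by = group_by)
  out
}

feature_vector <- function(length_nm, diameter_nm) {
  ar <- length_nm / diameter_nm
  cv <- function(x) {
    m <- mean(x)
    s <- sd(x)
    if (s == 0) {
      warning("degenerate variance: CV set to 0")
      return(0)
    }
    s / m
  }
  c(length_mean = mean(length_nm),
    length_cv = cv(length_nm),
    diameter_mean = mean(diameter_nm),
    diameter_cv = cv(diameter_nm),
    aspect_ratio_mean = mean(ar),
    aspect_ratio_skew = suppressWarnings(skewness_moment(ar)),
    length_skew = suppressWarnings(skewness_moment(length_nm)),
    diameter_skew = suppressWarnings(skewness_moment(diameter_nm)))
}

#' Extract the feature matrix from a feature table
#'
#' @param features output of \code{\link{compute_features}}.
#' @param variables which features to keep (default all eight).
#' @return numeric matrix with sample ids as rownames.
#' @export
feature_matrix <- function(features, variables = FEATURE_NAMES) {
  m <- as.matrix(features[, variables, drop = FALSE])
  rownames(m) <- features[[1]]
  storage.mode(m) <- "double"
  m
}
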