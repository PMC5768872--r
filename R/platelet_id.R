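#' Highest-density-region membership against a reference morphospace
#'
#' Operationalizes "outside the extant avian morphospace": a KDE is fitted
#' to the reference (non-platelet) measurements, the density threshold
#' delimiting the \code{hdr_level} highest-density region is the
#' \code{1 - hdr_level} quantile of the reference points' own density
#' values, and a measurement is outside when its density falls below that
#' threshold. The sample-level flag is true when the outside fraction
#' exceeds the majority rule.
#'
#' @param sample_points (length, diameter) measurements of one sample.
#' @param reference_points reference measurements (>= 50 rows).
#' @param hdr_level probability mass of the inside region, in (0, 1);
#'   default 0.95.
#' @param majority sample-level flag requires outside fraction strictly
#'   greater than this (default 0.5).
#' @param bandwidth per-axis bandwidth; default estimated from the
#'   reference by the shared Silverman rule.
#' @return list: \code{outside} (sample-level flag),
#'   \code{outside_fraction}, \code{outside_flags} (per measurement),
#'   \code{threshold}, \code{bandwidth}, \code{hdr_level}.
#' @export
morphospace_exclusion <- function(sample_points, reference_points,
                                  hdr_level = 0.95, majority = 0.5,
                                  bandwidth = NULL) {
  ref <- hdr_reference(reference_points, hdr_level, bandwidth)
  dens <- kde_eval(sample_points, ref$points, ref$bandwidth)
  flags <- dens < ref$threshold
  list(outside = mean(flags) > majority, outside_fraction = mean(flags),
       outside_flags = flags, threshold = ref$threshold,
       bandwidth = ref$bandwidth, hdr_level = hdr_level)
}

#' Precompute a highest-density-region reference
#'
#' Fits the reference KDE once and caches the HDR density threshold, so
#' per-sample membership tests do not re-evaluate the n x n reference
#' self-density. Accepts (and passes through) an already-built reference.
#'
#' @inheritParams morphospace_exclusion
#' @return an \code{hdr_reference} list: \code{points}, \code{bandwidth},
#'   \code{threshold}, \code{hdr_level}.
#' @export
hdr_reference <- function(reference_points, hdr_level = 0.95,
                          bandwidth = NULL) {
  if (inherits(reference_points, "hdr_reference")) return(reference_points)
  pts <- as_points(reference_points)
  if (nrow(pts) < 50L)
    stop("reference morphospace needs at least 50 measurements")
  stopifnot(hdr_level > 0, hdr_level < 1)
  if (is.null(bandwidth)) bandwidth <- shared_bandwidth(pts)
  ref_dens <- kde_eval(pts, pts, bandwidth)
  structure(list(points = pts, bandwidth = bandwidth,
                 threshold = quantile(ref_dens, 1 - hdr_level, names = FALSE),
                 hdr_level = hdr_level),
            class = "hdr_reference")
}

#' Two-criterion platelet call for one sample
#'
#' A sample is called \code{platelet} when (i) its measurements fall
#' outside the reference morphospace (HDR rule) and (ii) images show
#' stacking/moulding evidence; \code{non_platelet} when both are false.
#' When the criteria disagree, a 2-component Gaussian mixture on
#' (log length, log diameter) splits the sample, the component whose
#' centroid has the lower reference density is labelled platelet, and the
#' verdict is \code{mixed} with per-measurement flags. Criterion (ii) is an
#' input flag: it is assessed on SEM images, not computed here.
#'
#' @param sample_meas measurement rows of one sample, including
#'   \code{stacking_evidence}.
#' @param reference_points reference non-platelet measurements.
#' @param hdr_level,majority,bandwidth see
#'   \code{\link{morphospace_exclusion}}.
#' @param seed integer seed for the mixture initialization.
#' @return list: \code{sample_id}, \code{verdict}, \code{criterion_i},
#'   \code{criterion_ii}, \code{outside_fraction}, \code{platelet_flags}
#'   (per measurement), \code{hdr_level}.
#' @export
call_platelet <- function(sample_meas, reference_points, hdr_level = 0.95,
                          majority = 0.5, bandwidth = NULL, seed = 1L) {
  stopifnot("stacking_evidence" %in% names(sample_meas))
  crit_ii <- isTRUE(as_logical_col(sample_meas$stacking_evidence)[1])
  pts <- as_points(sample_meas)
  reference_points <- hdr_reference(reference_points, hdr_level, bandwidth)
  excl <- morphospace_exclusion(pts, reference_points, hdr_level = hdr_level,
                                majority = majority, bandwidth = bandwidth)
  crit_i <- excl$outside
  n <- nrow(pts)
  sid <- as.character(sample_meas$sample_id[1])
  if (crit_i && crit_ii) {
    verdict <- "platelet"
    flags <- rep(TRUE, n)
  } else if (!crit_i && !crit_ii) {
    verdict <- "non_platelet"
    flags <- rep(FALSE, n)
  } else {
    verdict <- "mixed"
    flags <- cluster_platelet_flags(pts, reference_points, excl, seed)
  }
  list(sample_id = sid, verdict = verdict, criterion_i = crit_i,
       criterion_ii = crit_ii, outside_fraction = excl$outside_fraction,
       platelet_flags = flags, hdr_level = hdr_level)
}

# 2-component Gaussian mixture on log axes; the component whose centroid
# has lower reference density is the platelet sub-population. Falls back
# to per-measurement HDR flags if the fit fails.
cluster_platelet_flags <- function(pts, reference_points, excl, seed) {
  fit <- NULL
  if (nrow(pts) >= 4L) {
    set.seed(derive_seed(seed, "gmm"))
    # bind mclustBIC locally: Mclust resolves it in the caller frame,
    # which fails under namespace-qualified calls
    mclustBIC <- mclust::mclustBIC
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(log(pts), G = 2L, verbose = FALSE)),
      error = function(e) NULL)
  }
  if (is.null(fit) || is.null(fit$classification)) {
    warning("mixture fit failed; falling back to per-measurement HDR flags")
    return(excl$outside_flags)
  }
  centroids <- exp(t(fit$parameters$mean))
  cen_dens <- kde_eval(centroids, hdr_reference(reference_points)$points,
                       excl$bandwidth)
  platelet_comp <- which.min(cen_dens)
  fit$classification == platelet_comp
}

#' Platelet calls for every sample in a measurement table
#'
#' @param measurements validated measurement table.
#' @param reference_points reference non-platelet measurements (e.g. the
#'   pooled extant library excluding platelet classes).
#' @inheritParams call_platelet
#' @return data.frame of per-sample calls with attribute \code{flags}: a
#'   named list of per-measurement platelet flags.
#' @export
call_platelets <- function(measurements, reference_points, hdr_level = 0.95,
                           majority = 0.5, bandwidth = NULL, seed = 1L) {
  reference_points <- hdr_reference(reference_points, hdr_level, bandwidth)
  bandwidth <- reference_points$bandwidth
  groups <- split(measurements, measurements$sample_id, drop = TRUE)
  calls <- lapply(groups, call_platelet, reference_points = reference_points,
                  hdr_level = hdr_level, majority = majority,
                  bandwidth = bandwidth, seed = seed)
  out <- do.call(rbind, lapply(calls, function(cl)
    data.frame(sample_id = cl$sample_id, verdict = cl$verdict,
               criterion_i = cl$criterion_i, criterion_ii = cl$criterion_ii,
               outside_fraction = cl$outside_fraction,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "flags") <- setNames(lapply(calls, `[[`, "platelet_flags"),
                                 vapply(calls, `[[`, "", "sample_id"))
  attr(out, "hdr_level") <- hdr_level
  out
}

#' Partition measurements for colour classification
#'
#' Nanostructures inferred as platelet-shaped are removed from the stream
#' feeding the colour classifier: samples called \code{platelet} drop out
#' entirely, \code{mixed} samples contribute only their non-platelet
#' measurements, and \code{non_platelet} samples pass through unchanged.
#' The partition is exhaustive and disjoint.
#'
#' @param calls output of \code{\link{call_platelets}}.
#' @param measurements the measurement table the calls were made on.
#' @return list: \code{non_platelet} and \code{platelet} measurement
#'   tables.
#' @export
partition_for_classification <- function(calls, measurements) {
  stopifnot(all(unique(measurements$sample_id) %in% calls$sample_id))
  flags <- attr(calls, "flags")
  keep <- logical(nrow(measurements))
  for (sid in unique(measurements$sample_id)) {
    idx <- which(measurements$sample_id == sid)
    keep[idx] <- !flags[[sid]]
  }
  if (!any(keep)) warning("all measurements platelet-flagged: empty classifier stream")
  list(non_platelet = measurements[keep, , drop = FALSE],
       platelet = measurements[!keep, , drop = FALSE])
}
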