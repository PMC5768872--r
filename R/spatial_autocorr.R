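#' Morphological distance matrix between samples
#'
#' Euclidean distance on z-scored feature vectors, so no feature's scale
#' dominates and the matrix is invariant under affine rescaling of any
#' feature.
#'
#' @param features feature data.frame (see \code{\link{compute_features}}).
#' @param variables features to use (default all eight).
#' @return symmetric matrix, zero diagonal, sample ids as dimnames.
#' @export
morph_distance <- function(features, variables = FEATURE_NAMES) {
  x <- feature_matrix(features, variables)
  if (any(!is.finite(x)))
    stop("sample(s) with missing features: ",
         paste(rownames(x)[!complete.cases(x)], collapse = ", "))
  z <- scale(x)
  z[, apply(x, 2, sd) == 0] <- 0
  as.matrix(dist(z))
}

#' Anatomical distance matrix between samples
#'
#' Euclidean mm distance on slab coordinates, or shortest-path hop counts
#' on a body-region adjacency graph when coordinates are unavailable.
#'
#' @param features feature data.frame carrying \code{slab_x_mm} and
#'   \code{slab_y_mm} (or \code{body_region} with \code{adjacency}).
#' @param adjacency optional two-column data.frame of adjacent region
#'   pairs; switches to graph-hop distance.
#' @return symmetric matrix, zero diagonal.
#' @export
anatomical_distance <- function(features, adjacency = NULL) {
  if (is.null(adjacency)) {
    xy <- cbind(features$slab_x_mm, features$slab_y_mm)
    if (any(is.na(xy))) {
      if (!all(is.na(xy)))
        stop("mixed coordinate availability: some samples lack slab_xy")
      stop("no slab coordinates; supply a region adjacency instead")
    }
    d <- as.matrix(dist(xy))
  } else {
    regions <- unique(c(adjacency[[1]], adjacency[[2]],
                        features$body_region))
    k <- length(regions)
    hop <- matrix(Inf, k, k, dimnames = list(regions, regions))
    diag(hop) <- 0
    for (i in seq_len(nrow(adjacency)))
      hop[adjacency[[1]][i], adjacency[[2]][i]] <-
      hop[adjacency[[2]][i], adjacency[[1]][i]] <- 1
    for (via in seq_len(k))  # Floyd-Warshall on the small region graph
      hop <- pmin(hop, outer(hop[, via], hop[via, ], `+`))
    if (any(!is.finite(hop)))
      stop("region adjacency graph is disconnected")
    d <- hop[features$body_region, features$body_region]
  }
  dimnames(d) <- list(features$sample_id, features$sample_id)
  d
}

#' Mantel permutation test
#'
#' Pearson correlation of the strictly-lower triangles of two distance
#' matrices; the null distribution is built by simultaneous row/column
#' permutation of the second matrix and the p-value is
#' \code{(1 + #{r_perm >= r_obs}) / (1 + n_permutations)} (one-sided,
#' positive association; \code{alternative = "two.sided"} doubles the
#' smaller tail).
#'
#' @param d1,d2 symmetric distance matrices with zero diagonals, same
#'   dimension, n >= 4.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed; the permutation stream is reproducible.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return list: \code{r}, \code{p}, \code{n_permutations}, \code{seed},
#'   \code{perm_r}.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999L, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  n <- nrow(d1)
  stopifnot(n >= 4L, all(dim(d2) == dim(d1)))
  if (max(abs(d1 - t(d1))) > 1e-8 || max(abs(d2 - t(d2))) > 1e-8)
    stop("distance matrices must be symmetric")
  if (any(abs(diag(d1)) > 1e-12) || any(abs(diag(d2)) > 1e-12))
    stop("distance matrices must have zero diagonals")
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  if (sd(v1) == 0 || sd(d2[lower]) == 0)
    stop("constant lower triangle: Mantel r undefined")
  r_obs <- cor(v1, d2[lower])
  set.seed(derive_seed(seed, "mantel"))
  perm_r <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n)
    cor(v1, d2[idx, idx][lower])
  }, 0)
  p_greater <- (1 + sum(perm_r >= r_obs)) / (1 + n_permutations)
  p <- if (alternative == "greater") p_greater else
    min(1, 2 * min(p_greater,
                   (1 + sum(perm_r <= r_obs)) / (1 + n_permutations)))
  list(r = r_obs, p = p, n_permutations = n_permutations, seed = seed,
       alternative = alternative, perm_r = perm_r)
}
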