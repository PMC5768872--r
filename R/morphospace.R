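#' Grid specification for a 2D morphospace density
#'
#' @param xlim,ylim ranges covering all points of every group compared
#'   (length and diameter, nm).
#' @param nx,ny grid points per axis (>= 32).
#' @return a \code{grid_spec} list with node coordinates.
#' @export
grid_spec <- function(xlim, ylim, nx = 151L, ny = 151L) {
  stopifnot(nx >= 32L, ny >= 32L, xlim[2] > xlim[1], ylim[2] > ylim[1])
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 nx = as.integer(nx), ny = as.integer(ny),
                 x = seq(xlim[1], xlim[2], length.out = nx),
                 y = seq(ylim[1], ylim[2], length.out = ny)),
            class = "grid_spec")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$xlim, b$xlim)) && isTRUE(all.equal(a$ylim, b$ylim)) &&
    a$nx == b$nx && a$ny == b$ny
}

#' Shared per-axis bandwidth from pooled data
#'
#' One bandwidth per axis from the pooled measurements of every group
#' (including the fossil), by the Silverman normal-reference rule
#' \code{1.06 * min(sd, IQR/1.34) * n^(-1/5)}. The same bandwidth must be
#' reused verbatim for every group's density so overlaps are comparable.
#'
#' @param points two-column matrix or data.frame of pooled (length,
#'   diameter) points, >= 10 rows.
#' @return numeric length-2 bandwidth (nm per axis).
#' @export
shared_bandwidth <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 10L) stop("need at least 10 pooled points for a bandwidth")
  bw <- apply(points, 2L, function(v) {
    s <- min(sd(v), (quantile(v, 0.75, names = FALSE) -
                       quantile(v, 0.25, names = FALSE)) / 1.34)
    1.06 * s * length(v)^(-1 / 5)
  })
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("zero-spread data: bandwidth undefined")
  unname(bw)
}

#' Default shared grid spanning pooled data
#'
#' Nodes span the pooled data range padded by \code{pad_bw} bandwidths per
#' side, so no group's mass is clipped.
#'
#' @param points pooled (length, diameter) points.
#' @param bandwidth per-axis bandwidth (see \code{\link{shared_bandwidth}}).
#' @param nx,ny grid resolution.
#' @param pad_bw padding in bandwidth units.
#' @return \code{\link{grid_spec}}.
#' @export
shared_grid <- function(points, bandwidth = shared_bandwidth(points),
                        nx = 151L, ny = 151L, pad_bw = 3) {
  points <- as_points(points)
  grid_spec(range(points[, 1]) + c(-1, 1) * pad_bw * bandwidth[1],
            range(points[, 2]) + c(-1, 1) * pad_bw * bandwidth[2],
            nx, ny)
}

as_points <- function(points) {
  if (is.data.frame(points)) {
    cols <- if (all(c("length_nm", "diameter_nm") %in% names(points)))
      c("length_nm", "diameter_nm") else names(points)[1:2]
    points <- as.matrix(points[, cols])
  }
  stopifnot(is.matrix(points), ncol(points) == 2L)
  storage.mode(points) <- "double"
  points
}

#' Fit a proportion-normalized 2D kernel density
#'
#' Gaussian product kernel evaluated on the grid, then converted to
#' proportions by dividing by its sum, so grid values sum to 1 and the
#' pointwise-minimum overlap statistic is well defined. Densities to be
#' compared must share grid and bandwidth.
#'
#' @param points (length, diameter) pairs, >= 3 rows, all inside the grid
#'   range (points outside raise an error rather than silently losing mass).
#' @param grid \code{\link{grid_spec}}.
#' @param bandwidth per-axis positive bandwidth.
#' @return a \code{morphospace_density}: grid, bandwidth, n, and an
#'   \code{nx x ny} matrix of non-negative proportions summing to 1.
#' @export
fit_density <- function(points, grid, bandwidth) {
  points <- as_points(points)
  stopifnot(inherits(grid, "grid_spec"), length(bandwidth) == 2L,
            all(bandwidth > 0))
  if (nrow(points) < 3L) stop("need at least 3 points for a density")
  if (any(points[, 1] < grid$xlim[1] | points[, 1] > grid$xlim[2] |
          points[, 2] < grid$ylim[1] | points[, 2] > grid$ylim[2]))
    stop("points fall outside the grid range; re-fit the grid over the ",
         "pooled data before comparing densities")
  ax <- dnorm(outer(grid$x, points[, 1], "-") / bandwidth[1]) / bandwidth[1]
  ay <- dnorm(outer(grid$y, points[, 2], "-") / bandwidth[2]) / bandwidth[2]
  values <- (ax %*% t(ay)) / nrow(points)
  values <- values / sum(values)
  structure(list(grid = grid, bandwidth = as.numeric(bandwidth),
                 n = nrow(points), values = values),
            class = "morphospace_density")
}

#' Evaluate a kernel density at arbitrary points
#'
#' Unnormalized (true-density-scale) Gaussian product-kernel density of
#' \code{data} evaluated at \code{eval_points}; used for highest-density
#' region membership.
#'
#' @param eval_points points at which to evaluate.
#' @param data reference points defining the density.
#' @param bandwidth per-axis bandwidth.
#' @return numeric vector of density values.
#' @export
kde_eval <- function(eval_points, data, bandwidth) {
  eval_points <- as_points(eval_points)
  data <- as_points(data)
  stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
  ax <- dnorm(outer(eval_points[, 1], data[, 1], "-") / bandwidth[1])
  ay <- dnorm(outer(eval_points[, 2], data[, 2], "-") / bandwidth[2])
  rowSums(ax * ay) / (nrow(data) * bandwidth[1] * bandwidth[2])
}

#' Proportional overlap of two morphospace densities
#'
#' The sum over the shared grid of the pointwise minima of the two
#' proportion-normalized densities: 1 for identical distributions, 0 for
#' disjoint ones.
#'
#' @param a,b \code{morphospace_density} objects on the same grid and
#'   bandwidth.
#' @return list with \code{overlap} in [0, 1] plus grid/bandwidth
#'   provenance.
#' @export
proportional_overlap <- function(a, b) {
  stopifnot(inherits(a, "morphospace_density"),
            inherits(b, "morphospace_density"))
  if (!same_grid(a$grid, b$grid))
    stop("densities were fitted on different grids")
  if (!isTRUE(all.equal(a$bandwidth, b$bandwidth)))
    stop("densities were fitted with different bandwidths")
  list(overlap = sum(pmin(a$values, b$values)),
       grid = a$grid, bandwidth = a$bandwidth, n_a = a$n, n_b = b$n)
}

#' Pairwise overlap matrix for labelled measurements
#'
#' Fits one density per group with a shared grid and bandwidth estimated
#' from the pooled points (fossil included) and returns the matrix of
#' pairwise proportional overlaps.
#'
#' @param measurements measurement table.
#' @param group_col column defining groups (default \code{colour_label};
#'   fossil samples are typically grouped under their own label first).
#' @param nx,ny grid resolution.
#' @param bandwidth optional fixed bandwidth; default estimated from pooled
#'   points.
#' @return list: \code{overlap} (symmetric matrix, unit diagonal),
#'   \code{bandwidth}, \code{grid}.
#' @export
overlap_matrix <- function(measurements, group_col = "colour_label",
                           nx = 151L, ny = 151L, bandwidth = NULL) {
  pts <- as_points(measurements)
  if (is.null(bandwidth)) bandwidth <- shared_bandwidth(pts)
  grid <- shared_grid(pts, bandwidth, nx = nx, ny = ny)
  groups <- split(as.data.frame(pts), measurements[[group_col]], drop = TRUE)
  dens <- lapply(groups, fit_density, grid = grid, bandwidth = bandwidth)
  k <- length(dens)
  ov <- matrix(1, k, k, dimnames = list(names(dens), names(dens)))
  if (k >= 2L)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
      ov[i, j] <- ov[j, i] <- proportional_overlap(dens[[i]], dens[[j]])$overlap
  list(overlap = ov, bandwidth = bandwidth, grid = grid)
}

#' Centroid-distance dispersion test
#'
#' Tests whether multivariate dispersion about the group centroid differs
#' between groups: each point's Euclidean distance to its own group
#' centroid is computed in z-scored (length, diameter) space (pooled sd per
#' axis, so the nm scale of length does not dominate), and a one-way linear
#' model of distance on group is fitted.
#'
#' @param measurements measurement table with a group column.
#' @param group_col grouping column (default \code{colour_label}).
#' @param standardize z-score each axis by the pooled sd first (default
#'   TRUE); FALSE computes distances on the raw nm scale.
#' @return list: per-group mean distances, \code{F}, \code{p}, df, and the
#'   per-point distances.
#' @export
centroid_distance_test <- function(measurements, group_col = "colour_label",
                                   standardize = TRUE) {
  pts <- as_points(measurements)
  grp <- factor(measurements[[group_col]])
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  if (any(table(grp) < 3L)) stop("each group needs at least 3 points")
  z <- if (standardize)
    scale(pts, center = TRUE, scale = apply(pts, 2, sd)) else pts
  cent <- apply(z, 2, function(v) tapply(v, grp, mean))
  dist_own <- sqrt(rowSums((z - cent[as.integer(grp), , drop = FALSE])^2))
  fit <- lm(dist_own ~ grp)
  an <- anova(fit)
  list(group_means = tapply(dist_own, grp, mean),
       F = an[1, "F value"], p = an[1, "Pr(>F)"],
       df = unname(an[, "Df"]), distances = dist_own, groups = grp)
}

#' Rarefaction of variance
#'
#' Assesses whether sampling adequately captures morphological variation:
#' for each subsample size, the variance statistic (by default the trace of
#' the (length, diameter) covariance) is recomputed over repeated
#' subsamples drawn without replacement, with a mean and a 2.5-97.5%
#' quantile band per size. At the full sample size the curve equals the
#' full-sample statistic exactly with zero spread.
#'
#' @param points (length, diameter) points.
#' @param sizes subsample sizes, each in [2, n].
#' @param n_reps subsamples per size (>= 100).
#' @param seed integer seed.
#' @param statistic function of a 2-column matrix returning a scalar.
#' @return data.frame: \code{size}, \code{mean}, \code{lower}, \code{upper};
#'   attributes \code{n_reps}, \code{seed}, \code{full_value}.
#' @export
rarefy_variance <- function(points, sizes, n_reps = 500L, seed = 1L,
                            statistic = function(m) sum(diag(cov(m)))) {
  points <- as_points(points)
  n <- nrow(points)
  stopifnot(all(sizes >= 2L), max(sizes) <= n, n_reps >= 100L)
  set.seed(derive_seed(seed, "rarefy"))
  full <- statistic(points)
  rows <- lapply(sort(unique(as.integer(sizes))), function(s) {
    if (s == n) {
      vals <- rep(full, 3L)
    } else {
      vals_all <- vapply(seq_len(n_reps), function(i)
        statistic(points[sample.int(n, s), , drop = FALSE]), 0)
      vals <- c(mean(vals_all),
                quantile(vals_all, c(0.025, 0.975), names = FALSE))
    }
    data.frame(size = s, mean = vals[1], lower = vals[2], upper = vals[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "full_value") <- full
  out
}
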