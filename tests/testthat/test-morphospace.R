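test_that("fitted density is a proper proportion surface", {
  set.seed(1)
  pts <- cbind(rnorm(200, 500, 40), rnorm(200, 200, 20))
  bw <- shared_bandwidth(pts)
  grid <- shared_grid(pts, bw, nx = 64, ny = 64)
  d <- fit_density(pts, grid, bw)
  expect_equal(sum(d$values), 1, tolerance = 1e-9)
  expect_true(all(d$values >= 0))
  # duplicating every point leaves the normalized surface unchanged
  d2 <- fit_density(rbind(pts, pts), grid, bw)
  expect_equal(d2$values, d$values, tolerance = 1e-12)
  # mode lands at the grid node nearest a tight cluster
  tight <- cbind(rnorm(50, 500, 1), rnorm(50, 200, 1))
  dt <- fit_density(tight, grid, bw)
  peak <- which(dt$values == max(dt$values), arr.ind = TRUE)
  expect_lt(abs(grid$x[peak[1]] - 500), diff(grid$x[1:2]) * 2)
  expect_lt(abs(grid$y[peak[2]] - 200), diff(grid$y[1:2]) * 2)
})

test_that("points outside the grid range raise a re-fit error", {
  pts <- cbind(runif(20, 0, 1), runif(20, 0, 1))
  grid <- grid_spec(c(0, 1), c(0, 1), 32, 32)
  expect_error(fit_density(rbind(pts, c(2, 0.5)), grid, c(0.1, 0.1)),
               "outside the grid")
})

test_that("grid KDE approximates the analytic normal density", {
  set.seed(2)
  n <- 20000
  pts <- cbind(rnorm(n), rnorm(n))
  grid <- grid_spec(c(-5, 5), c(-5, 5), 101, 101)
  bw <- c(0.35, 0.35)
  d <- fit_density(pts, grid, bw)
  # the KDE estimates the kernel-convolved density: a normal with
  # sd sqrt(1 + bw^2)
  s <- sqrt(1 + bw[1]^2)
  truth <- outer(dnorm(grid$x, sd = s), dnorm(grid$y, sd = s))
  truth <- truth / sum(truth)
  tv <- 0.5 * sum(abs(d$values - truth))
  expect_lt(tv, 0.02)
})

test_that("pooled bandwidth follows the Silverman rule and its guards", {
  set.seed(3)
  pts <- cbind(rnorm(1000), rnorm(1000))
  bw <- shared_bandwidth(pts)
  silverman <- 1.06 * 1 * 1000^(-1 / 5)
  expect_lt(abs(bw[1] - silverman) / silverman, 0.10)
  expect_lt(abs(bw[2] - silverman) / silverman, 0.10)
  # scale equivariance
  expect_equal(shared_bandwidth(pts * 7), bw * 7, tolerance = 1e-12)
  expect_error(shared_bandwidth(pts[1:5, ]), "at least 10")
  expect_error(shared_bandwidth(matrix(1, 20, 2)), "zero-spread")
})

test_that("overlap axioms: identity, symmetry, range, disjoint supports", {
  set.seed(4)
  a_pts <- cbind(rnorm(300, 400, 30), rnorm(300, 150, 15))
  b_pts <- cbind(rnorm(300, 460, 30), rnorm(300, 170, 15))
  far_pts <- cbind(rnorm(300, 5000, 30), rnorm(300, 2000, 15))
  pooled <- rbind(a_pts, b_pts, far_pts)
  bw <- shared_bandwidth(pooled)
  grid <- shared_grid(pooled, bw, nx = 128, ny = 128)
  da <- fit_density(a_pts, grid, bw)
  db <- fit_density(b_pts, grid, bw)
  df <- fit_density(far_pts, grid, bw)
  expect_equal(proportional_overlap(da, da)$overlap, 1, tolerance = 1e-12)
  oab <- proportional_overlap(da, db)$overlap
  expect_equal(oab, proportional_overlap(db, da)$overlap)
  expect_gte(oab, 0)
  expect_lte(oab, 1)
  expect_lt(proportional_overlap(da, df)$overlap, 1e-6)
  grid2 <- grid_spec(grid$xlim + 1, grid$ylim, grid$nx, grid$ny)
  expect_error(proportional_overlap(da, fit_density(b_pts, grid2, bw)),
               "different grids")
})

test_that("overlap decreases monotonically as equal densities translate apart", {
  set.seed(5)
  base <- cbind(rnorm(400), rnorm(400))
  grid <- grid_spec(c(-6, 12), c(-6, 6), 151, 151)
  bw <- c(0.3, 0.3)
  d0 <- fit_density(base, grid, bw)
  overlaps <- vapply(seq(0, 5, by = 0.5), function(delta) {
    shifted <- sweep(base, 2, c(delta, 0), "+")
    proportional_overlap(d0, fit_density(shifted, grid, bw))$overlap
  }, 0)
  expect_true(all(diff(overlaps) <= 1e-9))
})

test_that("overlap of offset unit normals approaches 2*pnorm(-1)", {
  # analytic: two unit-variance normals offset by delta have minimum
  # overlap 2*Phi(-delta/2)
  set.seed(6)
  n <- 8000
  a <- cbind(rnorm(n), rnorm(n))
  b <- cbind(rnorm(n) + 2, rnorm(n))
  grid <- grid_spec(c(-6, 8), c(-6, 6), 151, 151)
  bw <- c(0.12, 0.12)
  ov <- proportional_overlap(fit_density(a, grid, bw),
                             fit_density(b, grid, bw))$overlap
  expect_lt(abs(ov - 2 * pnorm(-1)), 0.02)
})

test_that("overlap is stable under grid refinement", {
  set.seed(7)
  a <- cbind(rnorm(500, 0, 1), rnorm(500, 0, 1))
  b <- cbind(rnorm(500, 1.2, 1), rnorm(500, 0, 1))
  bw <- c(0.4, 0.4)
  ovs <- vapply(c(76L, 151L), function(nn) {
    grid <- grid_spec(c(-6, 7), c(-6, 6), nn, nn)
    proportional_overlap(fit_density(a, grid, bw),
                         fit_density(b, grid, bw))$overlap
  }, 0)
  expect_lt(abs(diff(ovs)), 0.005)
})

test_that("overlap matrix agrees with an independent KDE route", {
  skip_if_not_installed("MASS")
  set.seed(8)
  pts <- cbind(rnorm(400, 500, 60), rnorm(400, 200, 25))
  grp <- rep(c("u", "v"), each = 200)
  meas <- data.frame(sample_id = grp, length_nm = pts[, 1],
                     diameter_nm = pts[, 2], colour_label = grp)
  om <- overlap_matrix(meas, nx = 101, ny = 101)
  bw <- om$bandwidth
  g <- om$grid
  ref <- lapply(split(as.data.frame(pts), grp), function(d) {
    k <- MASS::kde2d(d[, 1], d[, 2], h = 4 * bw, n = c(g$nx, g$ny),
                     lims = c(g$xlim, g$ylim))
    k$z / sum(k$z)
  })
  ov_ref <- sum(pmin(ref$u, ref$v))
  expect_equal(om$overlap["u", "v"], ov_ref, tolerance = 1e-6)
})

test_that("centroid-distance test: translation and scaling behaviour", {
  set.seed(9)
  a <- cbind(rnorm(50, 500, 30), rnorm(50, 200, 15))
  b <- sweep(a, 2, c(300, 100), "+")  # exact translated copy
  meas <- data.frame(length_nm = c(a[, 1], b[, 1]),
                     diameter_nm = c(a[, 2], b[, 2]),
                     colour_label = rep(c("a", "b"), each = 50))
  res <- centroid_distance_test(meas, standardize = FALSE)
  expect_lt(res$F, 1e-12)
  expect_equal(unname(res$group_means["a"]), unname(res$group_means["b"]))
  # scaling one group about its centroid scales its distances
  b3 <- sweep(sweep(a, 2, colMeans(a)) * 3, 2, colMeans(a), "+")
  meas3 <- data.frame(length_nm = c(a[, 1], b3[, 1]),
                      diameter_nm = c(a[, 2], b3[, 2]),
                      colour_label = rep(c("a", "b"), each = 50))
  res3 <- centroid_distance_test(meas3, standardize = FALSE)
  expect_equal(unname(res3$group_means["b"] / res3$group_means["a"]), 3,
               tolerance = 1e-9)
})

test_that("rarefaction curve: exact endpoint, determinism, unbiasedness", {
  set.seed(10)
  pts <- cbind(rnorm(200, 0, 2), rnorm(200, 0, 1))
  full <- sum(diag(cov(pts)))
  cur <- rarefy_variance(pts, sizes = c(10, 50, 200), n_reps = 300, seed = 5)
  expect_identical(cur, rarefy_variance(pts, sizes = c(10, 50, 200),
                                        n_reps = 300, seed = 5))
  at_n <- cur[cur$size == 200, ]
  expect_equal(at_n$mean, full)
  expect_equal(at_n$upper - at_n$lower, 0)
  at_50 <- cur[cur$size == 50, ]
  # subsampling without replacement keeps the n-1 estimator unbiased for
  # the full-sample value; SE from the rep spread
  se <- (at_50$upper - at_50$lower) / (2 * 1.96) / sqrt(300)
  expect_lt(abs(at_50$mean - full), 3 * se + 0.01 * full)
  expect_error(rarefy_variance(pts, sizes = 1, n_reps = 100), "sizes")
})
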