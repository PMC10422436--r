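test_that("LC is zero for a constant normal field", {
  plate <- make_tilted_plate(0, extent = 10, spacing = 1)
  cf <- local_curvature(compute_normals(plate, 3), window = 5)
  expect_equal(cf$lc, rep(0, nrow(plate)))
  expect_equal(cf$s_nx, rep(0, nrow(plate)))
})

test_that("LC of a half-up half-sideways window is sqrt(0.5)", {
  # 4 x 4 grid; an LC window of 15 covers the whole grid from every point,
  # so each point's window holds all 16 normals: 8 of (0,0,1), 8 of (1,0,0)
  cloud <- make_tilted_plate(0, extent = 3, spacing = 1)
  cloud <- compute_normals(cloud, 3)
  cloud$nx <- rep(c(1, 0), 8)
  cloud$ny <- 0
  cloud$nz <- rep(c(0, 1), 8)
  cf <- local_curvature(cloud, window = 15)
  expect_equal(cf$lc, rep(sqrt(0.25 + 0.25), 16), tolerance = 1e-12)
  # and the standalone statistic agrees
  expect_equal(lc_statistic(cbind(cloud$nx, cloud$ny, cloud$nz)),
               0.7071068, tolerance = 1e-7)
})

test_that("LC equals sqrt(1 - ||mean normal||^2) for unit normals", {
  set.seed(301)
  for (rep in 1:20) {
    N <- random_unit_normals(1000)
    direct <- lc_statistic(N)
    identity <- sqrt(1 - sum(colMeans(N)^2))
    expect_equal(direct, identity, tolerance = 1e-12)
  }
})

test_that("LC is invariant to rotation of the normal field", {
  set.seed(302)
  leaf <- make_blistered_leaf(extent = 20, spacing = 0.5, amplitude = 2,
                              wavelength = 6, footprint = "rectangle")
  cf <- local_curvature(compute_normals(leaf, 5), window = 9)
  R <- random_rotation()
  rot <- cf
  N <- cbind(cf$nx, cf$ny, cf$nz) %*% t(R)
  rot$nx <- N[, 1]; rot$ny <- N[, 2]; rot$nz <- N[, 3]
  cf_rot <- local_curvature(rot, window = 9)
  expect_lt(max(abs(cf_rot$lc - cf$lc)), 1e-9)
})

test_that("LC stays within [0, 1] on disordered fields", {
  set.seed(303)
  cloud <- point_cloud(data.frame(x = runif(500), y = runif(500),
                                  z = runif(500)))
  N <- random_unit_normals(500)
  cloud$nx <- N[, 1]; cloud$ny <- N[, 2]; cloud$nz <- N[, 3]
  cf <- local_curvature(cloud, window = 5, mode = "knn")
  expect_true(all(cf$lc >= 0 & cf$lc <= 1 + 1e-9))
  expect_equal(cf$lc, sqrt(cf$s_nx^2 + cf$s_ny^2 + cf$s_nz^2))
})

test_that("histograms bin correctly and conserve counts", {
  h <- lc_histogram(c(0.02, 0.07))
  expect_equal(nrow(h), 20)
  expect_equal(h$frequency[1:2], c(1L, 1L))
  expect_equal(sum(h$frequency), 2)

  h0 <- lc_histogram(rep(0, 7))
  expect_equal(h0$frequency[1], 7L)
  expect_equal(sum(h0$frequency[-1]), 0L)

  # values >= 1 land in the last (closed) bin
  h1 <- lc_histogram(c(1, 0.999, 1.0000001))
  expect_equal(h1$frequency[20], 3L)

  set.seed(304)
  v <- runif(10000)
  expect_equal(sum(lc_histogram(v)$frequency), 10000)

  expect_error(lc_histogram(v, bin_width = 0.03),
               class = "leafscan_error_param")
  expect_error(lc_histogram(numeric(0)), class = "leafscan_error_empty")
})

test_that("histogram centroid is the frequency-weighted bin-midpoint mean", {
  h <- lc_histogram(rep(0.32, 5))
  expect_equal(histogram_centroid(h), 0.325)

  # two occupied bins with midpoints 0.125 and 0.325, weights 1 and 3
  h <- lc_histogram(c(0.11, 0.31, 0.32, 0.33))
  expect_equal(histogram_centroid(h), (0.125 + 3 * 0.325) / 4)

  set.seed(305)
  v <- runif(5000)
  h <- lc_histogram(v)
  occupied <- h$midpoint[h$frequency > 0]
  lcg <- histogram_centroid(h)
  expect_gte(lcg, min(occupied))
  expect_lte(lcg, max(occupied))
})

test_that("smooth_fraction counts the sub-threshold share", {
  expect_equal(smooth_fraction(rep(0, 10)), 1)
  expect_equal(smooth_fraction(rep(0.9, 10)), 0)
  set.seed(306)
  v <- c(runif(25, 0, 0.49), runif(75, 0.51, 1))
  expect_equal(smooth_fraction(v), 0.25)
  expect_equal(smooth_fraction(v, threshold = 1), 1)
  expect_error(smooth_fraction(v, threshold = 0),
               class = "leafscan_error_param")
})

test_that("curvature_summary composes the pipeline deterministically", {
  plate <- make_tilted_plate(10, extent = 12, spacing = 0.5)
  s <- curvature_summary(plate)
  expect_equal(s$lcg, 0.025)        # all mass in the lowest bin
  expect_equal(s$smooth_fraction, 1)

  # mask of a homogeneous region changes nothing
  s2 <- curvature_summary(plate, mask = seq_len(nrow(plate)))
  expect_equal(s2$lcg, s$lcg)

  # blistered leaf: amplitude raises the centroid (same seed and geometry)
  lo <- curvature_summary(make_blistered_leaf(extent = 30, spacing = 0.5,
                                              amplitude = 0.5,
                                              wavelength = 10, seed = 42,
                                              footprint = "rectangle"))
  hi <- curvature_summary(make_blistered_leaf(extent = 30, spacing = 0.5,
                                              amplitude = 2,
                                              wavelength = 10, seed = 42,
                                              footprint = "rectangle"))
  expect_gt(hi$lcg, lo$lcg)
})
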