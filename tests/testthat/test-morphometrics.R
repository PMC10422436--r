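test_that("bounding box volume is exact on cubes and degenerate on plates", {
  corners <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  expect_equal(bounding_box_volume(corners), 1)

  R <- rot_z(45)
  rotated <- as.data.frame(as.matrix(corners) %*% t(R))
  names(rotated) <- c("x", "y", "z")
  expect_equal(bounding_box_volume(rotated), 2)  # sqrt(2) x sqrt(2) x 1

  plate <- make_tilted_plate(0, extent = 10, spacing = 1)
  expect_warning(v <- bounding_box_volume(plate), "degenerate")
  expect_equal(v, 0)
})

test_that("convex hull volume matches analytic solids", {
  corners <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  expect_equal(convex_hull_volume(corners), 1)

  # regular tetrahedron, edge 1: V = 1 / (6 sqrt(2))
  tet <- data.frame(x = c(0, 1, 0.5, 0.5),
                    y = c(0, 0, sqrt(3) / 2, sqrt(3) / 6),
                    z = c(0, 0, 0, sqrt(2 / 3)))
  expect_equal(convex_hull_volume(tet), 1 / (6 * sqrt(2)), tolerance = 1e-9)

  sphere <- make_sphere_surface(10, 50000, seed = 401)
  expect_equal(convex_hull_volume(sphere), 4 / 3 * pi * 1000,
               tolerance = 0.01)

  cube <- make_solid("cube", 10, 0.5, sampling = "boundary")
  expect_equal(convex_hull_volume(cube), 1000, tolerance = 1e-9)

  # interior points do not change the hull
  expect_error(convex_hull_volume(make_tilted_plate(0, 10, 1)),
               class = "leafscan_error_degenerate")
  expect_error(convex_hull_volume(data.frame(x = 1:10, y = 1:10, z = 1:10)),
               class = "leafscan_error_degenerate")
})

test_that("hull volume is rigid-motion invariant and dominated by the bbox", {
  set.seed(402)
  cloud <- point_cloud(data.frame(x = rnorm(300), y = rnorm(300),
                                  z = rnorm(300)))
  v <- convex_hull_volume(cloud)
  R <- random_rotation()
  moved <- rotate_cloud(cloud, R)
  moved$x <- moved$x + 17.3; moved$z <- moved$z + 4.2
  expect_equal(convex_hull_volume(moved) / v, 1, tolerance = 1e-9)

  for (i in 1:20) {
    cl <- data.frame(x = runif(30, -5, 5), y = runif(30, -5, 5),
                     z = runif(30, -5, 5))
    expect_gte(bounding_box_volume(cl), convex_hull_volume(cl))
  }
})

test_that("projected area and columnar volume follow raster geometry", {
  # raster-aligned plate: exactly (extent / cell)^2 cells
  g <- seq(0, 10 - 0.25, by = 0.25)
  aligned <- point_cloud(data.frame(x = rep(g, each = length(g)),
                                    y = rep(g, times = length(g)), z = 0))
  expect_equal(vertical_projected_area(aligned, 0.5), 100)

  # unaligned plate: within one boundary ring of the true footprint
  plate <- make_tilted_plate(0, extent = 40, spacing = 0.25)
  a <- vertical_projected_area(plate, cell = 0.5)
  expect_gte(a, 40^2)
  expect_lte(a, (40 / 0.5 + 1)^2 * 0.25)  # true footprint + one cell ring

  # stacking a second plate on top leaves the footprint unchanged
  stacked <- rbind(as.data.frame(plate),
                   within(as.data.frame(plate), z <- z + 5))
  expect_equal(vertical_projected_area(stacked, 0.5), a)

  # foreshortening: tilting by 60 degrees scales the footprint by cos(60)
  tilted <- make_tilted_plate(60, extent = 40, spacing = 0.25)
  expect_equal(vertical_projected_area(tilted, 0.5),
               a * cos(60 * pi / 180), tolerance = 0.05)

  cube <- make_solid("cube", 10, 0.25)
  expect_equal(columnar_volume(cube, 0.5), 1000, tolerance = 0.03)
  expect_equal(columnar_volume(plate, 0.5), 0)
  # columnar can exceed the bbox only by the raster ring on the footprint
  expect_lte(columnar_volume(cube, 0.5),
             bounding_box_volume(cube) * 1.1)

  expect_error(vertical_projected_area(plate, cell = 0),
               class = "leafscan_error_param")
})

test_that("voxelization counts occupied cells with set semantics", {
  one <- data.frame(x = 0.2, y = 0.3, z = 0.1)
  expect_equal(voxel_volume(one, 0.5), 0.125)

  cube <- make_solid("cube", 10, 0.25)  # cell-centred
  vox <- voxelize(cube, 0.5)
  expect_equal(nrow(vox), 8000)
  expect_equal(voxel_volume(cube, 0.5), 1000)

  doubled <- rbind(as.data.frame(cube), as.data.frame(cube))
  expect_equal(voxel_volume(doubled, 0.5), 1000)

  # occupancy volume of a solid converges from above: error halves or better
  # with double sampling/voxel resolution
  ball_c <- make_solid("ball", 10, 0.25)
  err1 <- voxel_volume(ball_c, 1) / (4 / 3 * pi * 1000) - 1
  err2 <- voxel_volume(ball_c, 0.5) / (4 / 3 * pi * 1000) - 1
  expect_gt(err1, 0)
  expect_gt(err2, 0)
  expect_lt(err2, err1 / 2 + 0.01)
  # surface-layer bound: overshoot below half a voxel layer (S * h / 2)
  expect_lt(err2 * 4 / 3 * pi * 1000, 4 * pi * 100 * 0.5 / 2)
})

test_that("compactness approaches 1 for solids and stays small for shells", {
  ball <- make_solid("ball", 20, 0.25)
  cmp <- compactness(ball, 0.5)
  expect_gt(cmp, 0.90)
  expect_lt(cmp, 1.05)

  shell <- make_sphere_surface(20, 50000, seed = 403)
  expect_lt(compactness(shell, 0.5), 0.2)

  rep <- volume_report(ball, voxel_size = 0.5)
  expect_equal(rep$compactness, rep$voxel_volume / rep$hull_volume)
  expect_gte(rep$bbox_volume, rep$hull_volume)
  expect_lte(rep$columnar_volume, rep$bbox_volume * 1.05)
})

test_that("plant dimensions match footprint oracles and rotation invariance", {
  tall <- data.frame(x = c(0, 1), y = c(0, 1), z = c(0, 50))
  expect_equal(plant_dimensions(tall)$height, 50)
  expect_equal(plant_dimensions(tall, ground_z = -10)$height, 60)

  ell <- ellipse_cloud(40, 20, spacing = 0.5)
  d <- plant_dimensions(ell)
  expect_equal(d$major_diameter, 80, tolerance = 0.5 / 80)
  expect_equal(d$minor_diameter, 40, tolerance = 0.5 / 40)

  # exhaustive direction-scan oracle at 0.1-degree steps
  widths <- direction_scan_widths(cbind(ell$x, ell$y))
  expect_equal(d$major_diameter, max(widths), tolerance = 1e-6)
  expect_equal(d$minor_diameter, min(widths), tolerance = 1e-3)

  # rotation about z leaves the diameters unchanged
  rotated <- rotate_cloud(ell, rot_z(33.3))
  d2 <- plant_dimensions(rotated)
  expect_equal(d2$major_diameter, d$major_diameter, tolerance = 1e-6)
  expect_equal(d2$minor_diameter, d$minor_diameter, tolerance = 1e-6)
  expect_gte(d$major_diameter, d$minor_diameter)
})

test_that("angle benchmark is exact on noiseless plates", {
  for (tilt in c(0, 45)) {
    plate <- make_tilted_plate(tilt, extent = 60, spacing = 0.5)
    bench <- estimate_region_angles(plate, cell_size = 10)
    g <- glance(bench)
    expect_equal(g$mean_angle, tilt, tolerance = 1e-6)
    expect_equal(g$sd_angle, 0, tolerance = 1e-6)
    expect_gte(g$n_cells, 1)
  }
  expect_error(estimate_region_angles(make_tilted_plate(0, 2, 1),
                                      cell_size = 0),
               class = "leafscan_error_param")
})

test_that("unsigned angles fold at zero while signed ones stay centred", {
  plate <- make_tilted_plate(0, extent = 40, spacing = 0.25, noise_sd = 0.3,
                             seed = 404)
  signed <- glance(estimate_region_angles(plate, 5, signed = TRUE))
  unsigned <- glance(estimate_region_angles(plate, 5, signed = FALSE))
  expect_lt(abs(signed$mean_angle), 0.5)
  expect_gt(unsigned$mean_angle, abs(signed$mean_angle))
  expect_true(all(estimate_region_angles(plate, 5,
                                         signed = FALSE)$angle >= 0))
})
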