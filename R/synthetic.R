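local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Synthetic tilted plate scan
#'
#' A regular grid on a flat plate of `extent` x `extent` mm, rotated by
#' `tilt` degrees about the y axis (so the noiseless plate satisfies
#' `z = tan(tilt) * x`), with Gaussian depth noise added along z. This
#' emulates the flat-plate procedure used to benchmark a scanner's angle
#' accuracy. The cloud is organized (row-major grid).
#'
#' Depth-only noise reflects how a turntable surface scanner errs: the
#' lateral sample positions come from the scan raster, the uncertainty is in
#' the measured depth.
#'
#' @param tilt Tilt in degrees, 0 <= tilt < 90.
#' @param extent Plate side length in mm (default 100).
#' @param spacing Grid spacing along the plate surface in mm (default 0.5).
#' @param noise_sd Gaussian depth-noise SD in mm (default 0).
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return An organized [point_cloud()].
#' @export
make_tilted_plate <- function(tilt, extent = 100, spacing = 0.5,
                              noise_sd = 0, seed = NULL) {
  if (tilt < 0 || tilt >= 90) {
    abort("`tilt` must be in [0, 90) degrees.", class = "leafscan_error_param")
  }
  if (spacing <= 0 || extent <= 0) {
    abort("`extent` and `spacing` must be positive.",
          class = "leafscan_error_param")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  g <- seq(-extent / 2, extent / 2, by = spacing)
  t <- tilt * pi / 180
  u <- rep(g, each = length(g))   # in-plane coordinate mapped to x
  v <- rep(g, times = length(g))  # in-plane coordinate mapped to y
  z <- u * sin(t)
  if (noise_sd > 0) z <- z + stats::rnorm(length(z), 0, noise_sd)
  point_cloud(tibble(x = u * cos(t), y = v, z = z),
              grid_shape = c(length(g), length(g)))
}

#' Synthetic blistered leaf lamina
#'
#' A leaf lamina with sinusoidal blisters: the height field
#' `z(x, y) = amplitude * E(x, y) * sin(2*pi*x / wavelength) *
#' sin(2*pi*y / wavelength)` plus Gaussian depth noise. With
#' `taper = TRUE` (default) the envelope
#' `E = max(0, 1 - (x/a)^2 - (y/b)^2)` damps the blisters towards the lamina
#' margin (real laminae flatten at the rim); with `taper = FALSE`, `E = 1`.
#' `a = extent/2` and `b = aspect * extent/2` are the lamina semi-axes.
#'
#' `footprint = "ellipse"` crops the cloud to the elliptical lamina
#' (unorganized result); `footprint = "rectangle"` keeps the full rectangular
#' grid (organized result, suitable for raster windows).
#'
#' @param extent Lamina length (mm) along x (default 60).
#' @param spacing Grid spacing in mm (default 0.5).
#' @param amplitude Blister amplitude in mm (>= 0; 0 gives a flat lamina).
#' @param wavelength Blister wavelength in mm (> 0, default 10).
#' @param noise_sd Gaussian depth-noise SD in mm (default 0).
#' @param seed Optional integer seed.
#' @param aspect Minor/major semi-axis ratio of the lamina (default 0.6).
#' @param footprint `"ellipse"` or `"rectangle"`.
#' @param taper Damp amplitude towards the margin (default TRUE).
#' @return A [point_cloud()]; organized iff `footprint = "rectangle"`.
#' @export
make_blistered_leaf <- function(extent = 60, spacing = 0.5, amplitude = 2,
                                wavelength = 10, noise_sd = 0, seed = NULL,
                                aspect = 0.6,
                                footprint = c("ellipse", "rectangle"),
                                taper = TRUE) {
  footprint <- match.arg(footprint)
  if (amplitude < 0) {
    abort("`amplitude` must be >= 0.", class = "leafscan_error_param")
  }
  if (wavelength <= 0 || spacing <= 0 || extent <= 0 || aspect <= 0) {
    abort("`extent`, `spacing`, `wavelength`, `aspect` must be positive.",
          class = "leafscan_error_param")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  g <- seq(-extent / 2, extent / 2, by = spacing)
  x <- rep(g, each = length(g))
  y <- rep(g, times = length(g))
  a <- extent / 2
  b <- aspect * extent / 2
  env <- if (taper) pmax(0, 1 - (x / a)^2 - (y / b)^2) else 1
  z <- amplitude * env * sin(2 * pi * x / wavelength) *
    sin(2 * pi * y / wavelength)
  if (noise_sd > 0) z <- z + stats::rnorm(length(z), 0, noise_sd)
  if (footprint == "rectangle") {
    point_cloud(tibble(x = x, y = y, z = z),
                grid_shape = c(length(g), length(g)))
  } else {
    keep <- (x / a)^2 + (y / b)^2 <= 1
    point_cloud(tibble(x = x[keep], y = y[keep], z = z[keep]))
  }
}

#' Uniformly sampled sphere surface
#'
#' `n_points` drawn uniformly on the surface of a sphere (normalized
#' Gaussian triples): every point is exactly `radius` mm from `center`, and
#' the true outward normal at each point is the radial direction -- an
#' analytic oracle for normal estimation and hull volume.
#'
#' @param radius Sphere radius in mm.
#' @param n_points Number of points (>= 4).
#' @param seed Optional integer seed.
#' @param center Length-3 centre (default origin).
#' @return An unorganized [point_cloud()].
#' @export
make_sphere_surface <- function(radius, n_points = 20000, seed = NULL,
                                center = c(0, 0, 0)) {
  if (radius <= 0) {
    abort("`radius` must be positive.", class = "leafscan_error_param")
  }
  if (n_points < 4) {
    abort("`n_points` must be >= 4.", class = "leafscan_error_param")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  m <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  m <- m / sqrt(rowSums(m^2))
  point_cloud(tibble(x = center[1] + radius * m[, 1],
                     y = center[2] + radius * m[, 2],
                     z = center[3] + radius * m[, 3]))
}

#' Volumetrically sampled solid (cube or ball)
#'
#' A regular lattice filling a solid of known volume, for volume-estimator
#' oracles. `sampling = "centres"` places lattice points at cell centres
#' `(k + 1/2) * pitch` (a cube of side `size` then occupies exactly
#' `(size/voxel)^3` voxels when `pitch` divides the voxel size);
#' `sampling = "boundary"` includes the boundary (the hull of a cube is then
#' exactly `size^3`).
#'
#' @param kind `"cube"` (side `size`, corner at the origin) or `"ball"`
#'   (radius `size`, centred at the origin).
#' @param size Side length or radius, mm.
#' @param pitch Lattice pitch, mm (default 0.25).
#' @param sampling `"centres"` (default) or `"boundary"`.
#' @return An unorganized [point_cloud()].
#' @export
make_solid <- function(kind = c("cube", "ball"), size = 10, pitch = 0.25,
                       sampling = c("centres", "boundary")) {
  kind <- match.arg(kind)
  sampling <- match.arg(sampling)
  if (size <= 0 || pitch <= 0) {
    abort("`size` and `pitch` must be positive.",
          class = "leafscan_error_param")
  }
  if (kind == "cube") {
    g <- if (sampling == "centres") {
      seq(pitch / 2, size - pitch / 2, by = pitch)
    } else {
      seq(0, size, by = pitch)
    }
    n <- length(g)
    point_cloud(tibble(x = rep(g, times = n * n),
                       y = rep(rep(g, each = n), times = n),
                       z = rep(g, each = n * n)))
  } else {
    r <- size
    g <- if (sampling == "centres") {
      k <- seq(floor(-r / pitch) - 1, ceiling(r / pitch))
      (k + 0.5) * pitch
    } else {
      seq(-r, r, by = pitch)
    }
    # slice-wise to keep peak memory low on fine lattices
    parts <- vector("list", length(g))
    r2 <- r^2
    yz <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
    ryz2 <- yz[, 1]^2 + yz[, 2]^2
    for (i in seq_along(g)) {
      keep <- ryz2 <= r2 - g[i]^2
      if (!any(keep)) next
      parts[[i]] <- cbind(g[i], yz[keep, 1], yz[keep, 2])
    }
    m <- do.call(rbind, parts)
    point_cloud(tibble(x = m[, 1], y = m[, 2], z = m[, 3]))
  }
}

#' Mock rosette plant
#'
#' `n_leaves` blistered laminae placed radially around a centre, each pitched
#' up by `elevation` degrees, emulating a leaf-lettuce rosette viewed by a
#' turntable scanner. Leaves are generated with [make_blistered_leaf()]
#' (elliptical footprint, margin taper), shifted so the lamina base sits at
#' the centre, rotated to its azimuth, and raised above the ground plane.
#' The result is unorganized (k-NN neighbourhoods downstream).
#'
#' @param n_leaves Number of leaves (>= 1, default 8).
#' @param leaf_extent Lamina length in mm (default 60).
#' @param amplitude Blister amplitude in mm (default 0).
#' @param wavelength Blister wavelength in mm (default 10).
#' @param elevation Leaf pitch above the ground plane, degrees (default 25).
#' @param spacing Lamina grid spacing in mm (default 0.75).
#' @param noise_sd Depth-noise SD in mm (default 0).
#' @param seed Optional integer seed.
#' @return An unorganized [point_cloud()].
#' @export
make_rosette <- function(n_leaves = 8, leaf_extent = 60, amplitude = 0,
                         wavelength = 10, elevation = 25, spacing = 0.75,
                         noise_sd = 0, seed = NULL) {
  if (n_leaves < 1) {
    abort("`n_leaves` must be >= 1.", class = "leafscan_error_param")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  el <- elevation * pi / 180
  parts <- vector("list", n_leaves)
  for (k in seq_len(n_leaves)) {
    leaf <- make_blistered_leaf(extent = leaf_extent, spacing = spacing,
                                amplitude = amplitude,
                                wavelength = wavelength,
                                noise_sd = noise_sd, seed = NULL,
                                footprint = "ellipse", taper = TRUE)
    m <- coords_matrix(leaf)
    # petiole end at x = 0, lamina along +x
    m[, 1] <- m[, 1] + leaf_extent / 2
    # pitch up about y (lamina rises with distance from the centre)
    xp <- m[, 1] * cos(el) - m[, 3] * sin(el)
    zp <- m[, 1] * sin(el) + m[, 3] * cos(el)
    m[, 1] <- xp
    m[, 3] <- zp
    # azimuth about z
    az <- 2 * pi * (k - 1) / n_leaves
    xr <- m[, 1] * cos(az) - m[, 2] * sin(az)
    yr <- m[, 1] * sin(az) + m[, 2] * cos(az)
    parts[[k]] <- cbind(xr, yr, m[, 3])
  }
  m <- do.call(rbind, parts)
  m[, 3] <- m[, 3] - min(m[, 3])
  point_cloud(tibble(x = m[, 1], y = m[, 2], z = m[, 3]))
}
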