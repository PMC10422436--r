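#' Axis-aligned bounding-box volume
#'
#' The product of the cloud's axis-aligned extents, in mm^3. The box is
#' gravity-aligned (z up, x--y from the scan frame) rather than a
#' minimum-volume oriented box: plant height is read off a box side, so the
#' box must share the plant's up axis. Planar or degenerate clouds return 0
#' with a warning.
#'
#' @param cloud A point cloud.
#' @return Volume in mm^3.
#' @export
bounding_box_volume <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  ext <- apply(coords_matrix(cloud), 2, function(v) diff(range(v)))
  if (any(ext == 0)) {
    warn("degenerate (planar or thinner) cloud: bounding-box volume is 0.")
    return(0)
  }
  prod(ext)
}

#' Convex-hull volume
#'
#' Exact volume of the 3D convex hull (the smallest convex polyhedron
#' containing the cloud), computed by quickhull.
#'
#' @param cloud A point cloud with at least 4 non-coplanar points.
#' @return Volume in mm^3.
#' @export
convex_hull_volume <- function(cloud) {
  convex_hull(cloud)$volume
}

#' @rdname convex_hull_volume
#' @return For `convex_hull`, a list with `volume` (mm^3), `area` (mm^2),
#'   `n_faces` and `n_vertices`.
#' @export
convex_hull <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 4) {
    abort("convex hull needs at least 4 points.",
          class = "leafscan_error_degenerate")
  }
  tryCatch(
    .quickhull3d(cloud$x, cloud$y, cloud$z),
    error = function(e) {
      abort(paste0("degenerate hull: ", conditionMessage(e)),
            class = "leafscan_error_degenerate")
    })
}

#' Vertical projected area
#'
#' The footprint area of the cloud viewed from directly above: points are
#' projected to the x--y plane and rasterized at `cell` mm; the area is the
#' number of occupied cells times `cell`^2. The raster grid is anchored at
#' the world origin.
#'
#' @param cloud A point cloud.
#' @param cell Raster cell size in mm (default 0.5, matching the voxel size).
#' @return Area in mm^2.
#' @export
vertical_projected_area <- function(cloud, cell = 0.5) {
  cloud <- as_point_cloud(cloud)
  if (cell <= 0) {
    abort("`cell` must be positive.", class = "leafscan_error_param")
  }
  ix <- floor(cloud$x / cell)
  iy <- floor(cloud$y / cell)
  key <- (ix - min(ix)) * (diff(range(iy)) + 1) + (iy - min(iy))
  length(unique(key)) * cell^2
}

#' Columnar-solid volume
#'
#' The bounding-box height (z extent) times the vertical projected area: the
#' volume of the column whose cross-section is the plant's footprint.
#'
#' @inheritParams vertical_projected_area
#' @return Volume in mm^3.
#' @export
columnar_volume <- function(cloud, cell = 0.5) {
  cloud <- as_point_cloud(cloud)
  diff(range(cloud$z)) * vertical_projected_area(cloud, cell = cell)
}

#' Voxelize a point cloud
#'
#' Converts the cloud into the set of occupied cubic voxels:
#' `index = floor(coordinate / voxel_size)` per axis, grid anchored at the
#' world origin. Duplicate points never double-count. Because occupancy is
#' all-or-nothing, the voxel volume of a dense solid overshoots the true
#' volume by up to about half a voxel layer at the surface (relative error
#' roughly `1.5 * voxel_size / r` for a ball of radius `r`).
#'
#' @param cloud A point cloud.
#' @param voxel_size Voxel edge length in mm (default 0.5).
#' @return A tibble of occupied voxel indices `ix`, `iy`, `iz` with
#'   attribute `voxel_size`.
#' @export
voxelize <- function(cloud, voxel_size = 0.5) {
  cloud <- as_point_cloud(cloud)
  if (voxel_size <= 0) {
    abort("`voxel_size` must be positive.", class = "leafscan_error_param")
  }
  ix <- floor(cloud$x / voxel_size)
  iy <- floor(cloud$y / voxel_size)
  iz <- floor(cloud$z / voxel_size)
  dx <- diff(range(ix)) + 1
  dy <- diff(range(iy)) + 1
  key <- ((ix - min(ix)) * dy + (iy - min(iy))) * (diff(range(iz)) + 1) +
    (iz - min(iz))
  keep <- !duplicated(key)
  out <- tibble(ix = as.integer(ix[keep]), iy = as.integer(iy[keep]),
                iz = as.integer(iz[keep]))
  attr(out, "voxel_size") <- voxel_size
  out
}

#' @rdname voxelize
#' @return For `voxel_volume`, the occupied-voxel count times
#'   `voxel_size`^3, in mm^3.
#' @export
voxel_volume <- function(cloud, voxel_size = 0.5) {
  nrow(voxelize(cloud, voxel_size = voxel_size)) * voxel_size^3
}

#' Canopy compactness
#'
#' Voxel volume divided by convex-hull volume. The closer to 1, the more the
#' plant fills its own hull with leaf material rather than air; a
#' surface-only shell (e.g. an open rosette) scores far below 1.
#'
#' @param cloud A point cloud with a non-degenerate hull.
#' @param voxel_size Voxel edge length in mm (default 0.5).
#' @return Dimensionless ratio.
#' @export
compactness <- function(cloud, voxel_size = 0.5) {
  voxel_volume(cloud, voxel_size = voxel_size) / convex_hull_volume(cloud)
}

#' All four volume estimators plus compactness
#'
#' @param cloud A point cloud.
#' @param voxel_size Voxel edge (mm, default 0.5).
#' @param cell Raster cell for the projected area (mm, default =
#'   `voxel_size`).
#' @return A one-row tibble: `bbox_volume`, `hull_volume`, `columnar_volume`,
#'   `voxel_volume` (mm^3), `compactness`, `voxel_size`, `cell`.
#' @export
volume_report <- function(cloud, voxel_size = 0.5, cell = voxel_size) {
  cloud <- as_point_cloud(cloud)
  hull <- convex_hull_volume(cloud)
  vox <- voxel_volume(cloud, voxel_size = voxel_size)
  tibble(bbox_volume = bounding_box_volume(cloud),
         hull_volume = hull,
         columnar_volume = columnar_volume(cloud, cell = cell),
         voxel_volume = vox,
         compactness = vox / hull,
         voxel_size = voxel_size,
         cell = cell)
}
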