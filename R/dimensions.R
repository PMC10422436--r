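#' Ruler-equivalent plant dimensions
#'
#' Height is measured from `ground_z` (default: the cloud's minimum z) to the
#' top of the plant. The major diameter is the longest distance across the
#' plant viewed from above (the diameter of the projected convex hull); the
#' minor diameter is the minimal width of the projected hull (the smallest
#' distance between two parallel lines enclosing it) -- the way a ruler
#' measures a rosette's narrow side. Both are invariant to rotation about z.
#'
#' @param cloud A point cloud with at least 2 points.
#' @param ground_z Ground height in mm; defaults to `min(z)`.
#' @param cell Raster cell for the projected area (mm, default 0.5).
#' @return A one-row tibble: `height`, `major_diameter`, `minor_diameter`
#'   (mm), `projected_area` (mm^2).
#' @export
plant_dimensions <- function(cloud, ground_z = NULL, cell = 0.5) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 2) {
    abort("plant_dimensions needs at least 2 points.",
          class = "leafscan_error_input")
  }
  ground_z <- ground_z %||% min(cloud$z)
  xy <- cbind(cloud$x, cloud$y)
  w <- hull_width_2d(xy)
  tibble(height = max(cloud$z) - ground_z,
         major_diameter = w$major,
         minor_diameter = w$minor,
         projected_area = vertical_projected_area(cloud, cell = cell))
}

# diameter and minimal width of the 2D convex hull.
# major = max pairwise distance over hull vertices; minor = min over hull
# edges of the max perpendicular distance of any vertex to that edge's line
# (the minimal width of a convex polygon is attained at an edge).
hull_width_2d <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) == 1) return(list(major = 0, minor = 0))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  V <- xy[h, , drop = FALSE]
  m <- nrow(V)
  major <- sqrt(max(stats::dist(V)^2))
  if (m < 3) return(list(major = major, minor = 0))
  minor <- Inf
  for (i in seq_len(m)) {
    a <- V[i, ]
    b <- V[if (i == m) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    d <- abs((xy[, 1] - a[1]) * nrm[1] + (xy[, 2] - a[2]) * nrm[2])
    minor <- min(minor, max(d))
  }
  list(major = major, minor = minor)
}

#' Tilted-plate angle-estimation benchmark
#'
#' Divides the cloud into square cells on the x--y plane, fits a plane to
#' each cell ([fit_plane()]) and reports the per-cell surface tilt. This is
#' the procedure used to validate a scanner's angle accuracy against a flat
#' plate tilted by a known angle: the spread of per-cell angles shrinks as
#' the cell grows.
#'
#' With `signed = TRUE` (default) the angle is the signed tilt about the y
#' axis, `atan` of the fitted x-slope -- appropriate for the plate bench,
#' where the tilt axis is known and an unsigned angle would be biased upward
#' near 0 degrees. With `signed = FALSE` the angle is `acos(|nz|)`, the
#' unsigned tilt from horizontal, meaningful for arbitrary surfaces. The
#' plane is fitted with `axis = "z"` (depth noise lives in z).
#'
#' Cells with fewer than `min_points` points, collinear content, or -- to
#' keep plate-edge slivers from dominating the spread -- a point span smaller
#' than `min_fill * cell_size` in x or y, are skipped and counted.
#'
#' @param cloud A plate-like point cloud.
#' @param cell_size Cell edge in mm (e.g. 1, 5, 10).
#' @param signed Report signed tilt about y (default) or unsigned
#'   `acos(|nz|)`.
#' @param min_points Minimum points per cell (default 3).
#' @param min_fill Minimum point span per cell, as a fraction of
#'   `cell_size` (default 0.5).
#' @return A tibble of class `angle_bench`, one row per used cell:
#'   `cell_x`, `cell_y`, `n`, `angle` (degrees), with attributes `cell_size`
#'   and `n_skipped`. Use [glance()] for the mean/SD summary.
#' @export
estimate_region_angles <- function(cloud, cell_size, signed = TRUE,
                                   min_points = 3, min_fill = 0.5) {
  cloud <- as_point_cloud(cloud)
  if (cell_size <= 0) {
    abort("`cell_size` must be positive.", class = "leafscan_error_param")
  }
  ix <- floor(cloud$x / cell_size)
  iy <- floor(cloud$y / cell_size)
  key <- paste(ix, iy)
  groups <- split(seq_len(nrow(cloud)), key)
  P <- coords_matrix(cloud)
  span <- min_fill * cell_size
  rows <- vector("list", length(groups))
  skipped <- 0L
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    if (length(idx) < min_points) { skipped <- skipped + 1L; next }
    px <- P[idx, 1]; py <- P[idx, 2]
    if (diff(range(px)) < span || diff(range(py)) < span) {
      skipped <- skipped + 1L; next
    }
    fit <- fit_plane_core(P[idx, , drop = FALSE], axis = "z")
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    ang <- if (signed) {
      # oriented normal is (-a, -b, 1)/len: signed tilt about y = atan(a)
      atan2(-fit$normal[1], fit$normal[3]) * 180 / pi
    } else {
      plane_tilt_deg(fit$normal)
    }
    rows[[gi]] <- c(ix[idx[1]], iy[idx[1]], length(idx), ang)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    abort("no valid cell: every cell was too small or degenerate.",
          class = "leafscan_error_degenerate")
  }
  m <- do.call(rbind, rows)
  out <- tibble(cell_x = as.integer(m[, 1]), cell_y = as.integer(m[, 2]),
                n = as.integer(m[, 3]), angle = m[, 4])
  attr(out, "cell_size") <- cell_size
  attr(out, "n_skipped") <- skipped
  attr(out, "signed") <- signed
  class(out) <- c("angle_bench", class(out))
  out
}

#' @export
glance.angle_bench <- function(x, ...) {
  tibble(cell_size = attr(x, "cell_size"),
         n_cells = nrow(x),
         n_skipped = attr(x, "n_skipped"),
         mean_angle = mean(x$angle),
         sd_angle = stats::sd(x$angle))
}

#' @export
tidy.angle_bench <- function(x, ...) as_tibble(x)
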