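#' Point-cloud tibbles
#'
#' A point cloud is a tibble with numeric columns `x`, `y`, `z` (millimetres;
#' +z is "up", the x--y plane is the ground) and, optionally, integer colour
#' columns `r`, `g`, `b` in 0--255. Clouds scanned as a raster ("organized"
#' clouds) additionally carry a `grid_shape` attribute `c(rows, cols)`; points
#' are stored row-major, so raster windows such as the 7 x 7 neighbourhood of
#' a point are index windows in this grid.
#'
#' @param data A data frame with columns `x`, `y`, `z` and optionally
#'   `r`, `g`, `b`.
#' @param grid_shape Optional integer vector `c(rows, cols)`; `rows * cols`
#'   must equal the number of points.
#' @return A `point_cloud` tibble.
#' @examples
#' pc <- point_cloud(data.frame(x = c(0, 1), y = c(0, 0), z = c(0, 0)))
#' is_organized(pc)
#' @export
point_cloud <- function(data, grid_shape = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns x, y, z.",
          class = "leafscan_error_input")
  }
  missing_cols <- setdiff(c("x", "y", "z"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "leafscan_error_input")
  }
  out <- as_tibble(data)
  if (nrow(out) < 1) {
    abort("a point cloud needs at least one point.",
          class = "leafscan_error_empty")
  }
  coords <- as.matrix(out[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("point coordinates must all be finite.",
          class = "leafscan_error_input")
  }
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 2 || any(grid_shape < 1) ||
        prod(grid_shape) != nrow(out)) {
      abort("`grid_shape` must be c(rows, cols) with rows * cols == n points.",
            class = "leafscan_error_input")
    }
  }
  new_point_cloud(out, grid_shape)
}

new_point_cloud <- function(data, grid_shape = NULL) {
  attr(data, "grid_shape") <- grid_shape
  class(data) <- unique(c("point_cloud", class(data)))
  data
}

#' @rdname point_cloud
#' @param x An object to test or coerce.
#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

#' @rdname point_cloud
#' @export
is_organized <- function(x) !is.null(attr(x, "grid_shape"))

#' @rdname point_cloud
#' @export
grid_shape <- function(x) attr(x, "grid_shape")

#' @rdname point_cloud
#' @export
as_point_cloud <- function(x, grid_shape = NULL) {
  if (is_point_cloud(x) && is.null(grid_shape)) {
    gs <- grid_shape(x)
    if (!is.null(gs) && prod(gs) != nrow(x)) {
      attr(x, "grid_shape") <- NULL
    }
    return(x)
  }
  gs <- grid_shape %||% grid_shape(x)
  # drop a stale grid shape (e.g. after row-binding data frames)
  if (!is.null(gs) && prod(gs) != nrow(x)) gs <- NULL
  point_cloud(as.data.frame(x), grid_shape = gs)
}

# coordinates as an n x 3 matrix
coords_matrix <- function(cloud) {
  as.matrix(as.data.frame(cloud)[, c("x", "y", "z")])
}

has_colors <- function(cloud) all(c("r", "g", "b") %in% names(cloud))

has_normals <- function(cloud) all(c("nx", "ny", "nz") %in% names(cloud))

#' Subset a point cloud with a region mask
#'
#' Masks select a region of interest (for instance a manually cut-out leaf
#' lamina, excluding margin and midrib) by point index. Mask *files* are
#' 0-based (see [read_mask()]); within R, indices are ordinary 1-based row
#' indices.
#'
#' @param cloud A point cloud (or any data frame with x, y, z).
#' @param mask Integer vector of 1-based point indices, e.g. from
#'   [read_mask()].
#' @return The subset `point_cloud`, in the original relative order. The
#'   result is unorganized (a masked raster is no longer a full grid) unless
#'   the mask selects every point.
#' @export
apply_mask <- function(cloud, mask) {
  cloud <- as_point_cloud(cloud)
  mask <- as.integer(mask)
  if (length(mask) == 0) {
    abort("mask selects no points.", class = "leafscan_error_empty")
  }
  if (anyDuplicated(mask)) {
    abort("mask indices must be unique.", class = "leafscan_error_input")
  }
  bad <- mask[mask < 1 | mask > nrow(cloud)]
  if (length(bad) > 0) {
    abort(sprintf("mask index %d is out of range (cloud has %d points).",
                  bad[1], nrow(cloud)),
          class = "leafscan_error_input")
  }
  mask <- sort(mask)
  keep_grid <- length(mask) == nrow(cloud)
  out <- as_tibble(as.data.frame(cloud)[mask, , drop = FALSE])
  new_point_cloud(out, if (keep_grid) grid_shape(cloud) else NULL)
}

#' @export
print.point_cloud <- function(x, ...) {
  gs <- grid_shape(x)
  org <- if (is.null(gs)) "unorganized"
         else sprintf("organized %d x %d", gs[1], gs[2])
  cat(sprintf("# Point cloud: %d points (%s), mm\n", nrow(x), org))
  NextMethod()
}
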