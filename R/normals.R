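check_window <- function(window) {
  if (length(window) != 1 || is.na(window) || window < 3 ||
      window %% 2 == 0) {
    abort("`window` must be an odd integer >= 3.",
          class = "leafscan_error_param")
  }
  as.integer(window)
}

resolve_mode <- function(cloud, mode) {
  mode <- match.arg(mode, c("auto", "grid", "knn"))
  if (mode == "auto") mode <- if (is_organized(cloud)) "grid" else "knn"
  if (mode == "grid" && !is_organized(cloud)) {
    abort("grid mode needs an organized cloud (grid_shape attribute).",
          class = "leafscan_error_param")
  }
  mode
}

# neighbourhood index matrix: one row per point, NA-padded.
# grid mode: the s x s raster window centred on each point, clipped at the
# borders. knn mode: the s^2 Euclidean-nearest points (self included).
neighbor_matrix <- function(cloud, window, mode) {
  window <- check_window(window)
  mode <- resolve_mode(cloud, mode)
  n <- nrow(cloud)
  if (mode == "grid") {
    gs <- grid_shape(cloud)
    nr <- gs[1]; nc <- gs[2]
    h <- (window - 1L) %/% 2L
    row_i <- rep(seq_len(nr), each = nc)
    col_i <- rep(seq_len(nc), times = nr)
    offs <- expand.grid(dr = -h:h, dc = -h:h)
    k <- nrow(offs)
    out <- matrix(NA_integer_, nrow = n, ncol = k)
    for (j in seq_len(k)) {
      rr <- row_i + offs$dr[j]
      cc <- col_i + offs$dc[j]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (rr - 1L) * nc + cc
      idx[!ok] <- NA_integer_
      out[, j] <- idx
    }
    out
  } else {
    k <- window^2
    if (n < k) {
      abort(sprintf("knn mode with window %d needs at least %d points (%d).",
                    window, k, n),
            class = "leafscan_error_param")
    }
    RANN::nn2(coords_matrix(cloud), k = k)$nn.idx
  }
}

#' Select the neighbourhood of one point
#'
#' In grid mode (organized clouds) the neighbourhood is the `window` x
#' `window` raster window centred on the point, clipped at the grid borders.
#' In knn mode it is the `window`^2 Euclidean-nearest points, the query point
#' included.
#'
#' @param cloud A point cloud.
#' @param index 1-based point index.
#' @param window Odd integer >= 3 (points per window side).
#' @param mode `"auto"`, `"grid"`, or `"knn"`.
#' @return Integer vector of 1-based point indices.
#' @export
select_neighbors <- function(cloud, index, window = 7,
                             mode = c("auto", "grid", "knn")) {
  cloud <- as_point_cloud(cloud)
  window <- check_window(window)
  mode <- resolve_mode(cloud, mode)
  index <- as.integer(index)
  if (index < 1 || index > nrow(cloud)) {
    abort("`index` out of range.", class = "leafscan_error_param")
  }
  if (mode == "grid") {
    gs <- grid_shape(cloud)
    nr <- gs[1]; nc <- gs[2]
    h <- (window - 1L) %/% 2L
    r0 <- (index - 1L) %/% nc + 1L
    c0 <- (index - 1L) %% nc + 1L
    rr <- pmax(1L, r0 - h):pmin(nr, r0 + h)
    cc <- pmax(1L, c0 - h):pmin(nc, c0 + h)
    as.integer(outer((rr - 1L) * nc, cc, `+`))
  } else {
    k <- window^2
    if (nrow(cloud) < k) {
      abort(sprintf("knn mode with window %d needs at least %d points.",
                    window, k),
            class = "leafscan_error_param")
    }
    as.integer(RANN::nn2(coords_matrix(cloud),
                         coords_matrix(cloud)[index, , drop = FALSE],
                         k = k)$nn.idx)
  }
}

# least-squares plane through a small neighbourhood.
# Axis selection: provisional total-least-squares normal (smallest principal
# direction of the centred points); the ordinary-LSQ form regresses the axis
# with the largest |provisional normal| component on the other two -- each
# form is ill-conditioned when the plane is parallel to its dependent axis.
# Returns NULL for degenerate (collinear / too small) neighbourhoods.
fit_plane_core <- function(P, axis = "auto") {
  n <- nrow(P)
  if (n < 3) return(NULL)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  C <- crossprod(Pc) / n
  ev <- eigen(C, symmetric = TRUE)
  # collinear: the two smallest principal variances both vanish
  if (ev$values[2] <= max(ev$values[1] * 1e-12, 1e-300)) return(NULL)
  if (axis == "auto") {
    prov <- ev$vectors[, 3]
    dep <- which.max(abs(prov))
  } else {
    dep <- match(axis, c("x", "y", "z"))
  }
  ind <- setdiff(1:3, dep)
  A <- cbind(P[, ind[1]], P[, ind[2]], 1)
  fit <- tryCatch(qr.coef(qr(A), P[, dep]), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) return(NULL)
  a <- fit[1]; b <- fit[2]; cc <- fit[3]
  nrm <- numeric(3)
  nrm[dep] <- -1
  nrm[ind[1]] <- a
  nrm[ind[2]] <- b
  len <- sqrt(sum(nrm^2))
  nrm <- nrm / len
  # perpendicular RMS residual (mm): dependent-axis residual times |n_dep|
  res <- P[, dep] - A %*% fit
  rms <- sqrt(mean(res^2)) / len
  list(a = a, b = b, c = cc, axis = c("x", "y", "z")[dep],
       normal = orient_vec(nrm), rms_residual = rms, n = n)
}

orient_vec <- function(v) {
  flip <- v[3] < 0 || (v[3] == 0 && (v[2] < 0 || (v[2] == 0 && v[1] < 0)))
  if (flip) -v else v
}

#' Fit a least-squares plane to 3D points
#'
#' Solves one of the three ordinary least-squares plane forms
#' `z = ax + by + c`, `y = ax + bz + c`, or `x = ay + bz + c`. With
#' `axis = "auto"` the dependent axis is the one with the largest absolute
#' component of a provisional total-least-squares normal, so the solved form
#' is always well conditioned. The unit normal is derived from the
#' coefficients and oriented into the +z hemisphere (ties broken towards
#' +y, then +x).
#'
#' @param points A data frame or matrix of at least 3 non-collinear points
#'   with columns x, y, z.
#' @param axis `"auto"`, or force the dependent axis: `"z"`, `"y"`, `"x"`.
#' @return An object of class `plane_fit`: coefficients `a`, `b`, `c`, the
#'   solved `axis`, the oriented unit `normal`, the perpendicular
#'   `rms_residual` (mm) and the number of points `n`. Use [tidy()] /
#'   [glance()] for tibble views.
#' @examples
#' fit_plane(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
#'                      z = c(0, 0, 0, 0)))
#' @export
fit_plane <- function(points, axis = c("auto", "z", "y", "x")) {
  axis <- match.arg(axis)
  if (is.data.frame(points)) {
    P <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  } else {
    P <- as.matrix(points)
    if (ncol(P) != 3) {
      abort("`points` must have three columns (x, y, z).",
            class = "leafscan_error_input")
    }
    colnames(P) <- c("x", "y", "z")
  }
  if (nrow(P) < 3) {
    abort("plane fitting needs at least 3 points.",
          class = "leafscan_error_degenerate")
  }
  fit <- fit_plane_core(P, axis = axis)
  if (is.null(fit)) {
    abort("degenerate input: points are collinear (or coincident).",
          class = "leafscan_error_degenerate")
  }
  structure(fit, class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  dep <- x$axis
  ind <- setdiff(c("x", "y", "z"), dep)
  cat(sprintf("Plane fit: %s = %.6g %s + %.6g %s + %.6g\n",
              dep, x$a, ind[1], x$b, ind[2], x$c))
  cat(sprintf("  normal (%.4f, %.4f, %.4f), tilt %.3f deg, rms %.4g mm, n = %d\n",
              x$normal[1], x$normal[2], x$normal[3],
              plane_tilt_deg(x$normal), x$rms_residual, x$n))
  invisible(x)
}

plane_tilt_deg <- function(normal) {
  acos(pmin(1, abs(normal[3]))) * 180 / pi
}

#' @export
tidy.plane_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @export
glance.plane_fit <- function(x, ...) {
  tibble(axis = x$axis,
         nx = x$normal[1], ny = x$normal[2], nz = x$normal[3],
         tilt_deg = plane_tilt_deg(x$normal),
         rms_residual = x$rms_residual,
         n = x$n)
}

#' Estimate per-point surface normals
#'
#' For every point, a plane is fitted by ordinary least squares to its local
#' neighbourhood (raster window on organized clouds, k-nearest neighbours
#' otherwise; see [select_neighbors()]) and the unit normal of that plane is
#' taken as the point's surface normal. Normals are oriented into the +z
#' hemisphere ([orient_normals()]): plants are scanned upright, so an
#' upward-facing leaf has normal (0, 0, 1). Points with degenerate
#' (collinear, or under-filled border) neighbourhoods inherit the normal of
#' the nearest valid point; their count is reported via a message and the
#' `n_degenerate` attribute.
#'
#' @param cloud A point cloud.
#' @param window Odd integer >= 3, points per window side (default 7).
#' @param mode `"auto"` (grid when organized, else knn), `"grid"`, `"knn"`.
#' @param min_points Minimum surviving points in a clipped grid window for a
#'   fit (default 4); smaller neighbourhoods are degenerate.
#' @return The cloud with unit-normal columns `nx`, `ny`, `nz` added and
#'   attributes `normals_window`, `normals_mode`, `n_degenerate`.
#' @export
compute_normals <- function(cloud, window = 7,
                            mode = c("auto", "grid", "knn"),
                            min_points = 4) {
  cloud <- as_point_cloud(cloud)
  window <- check_window(window)
  mode <- resolve_mode(cloud, mode)
  n <- nrow(cloud)
  if (mode == "knn" && n < window^2) {
    abort(sprintf(
      "cloud too small: knn normals with window %d need >= %d points (%d).",
      window, window^2, n),
      class = "leafscan_error_param")
  }
  nbr <- neighbor_matrix(cloud, window, mode)
  P <- coords_matrix(cloud)
  N <- matrix(NA_real_, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    idx <- nbr[i, ]
    idx <- idx[!is.na(idx)]
    if (length(idx) < min_points) next
    fit <- fit_plane_core(P[idx, , drop = FALSE])
    if (!is.null(fit)) N[i, ] <- fit$normal
  }
  bad <- which(is.na(N[, 1]))
  if (length(bad) == n) {
    abort("all neighbourhoods are degenerate; cannot estimate normals.",
          class = "leafscan_error_degenerate")
  }
  if (length(bad) > 0) {
    good <- which(!is.na(N[, 1]))
    nn <- RANN::nn2(P[good, , drop = FALSE], P[bad, , drop = FALSE], k = 1)
    N[bad, ] <- N[good[nn$nn.idx[, 1]], , drop = FALSE]
    inform(sprintf(
      "%d degenerate neighbourhood(s) inherited the nearest valid normal.",
      length(bad)))
  }
  out <- cloud
  out$nx <- N[, 1]; out$ny <- N[, 2]; out$nz <- N[, 3]
  out <- new_point_cloud(as_tibble(out), grid_shape(cloud))
  attr(out, "normals_window") <- window
  attr(out, "normals_mode") <- mode
  attr(out, "n_degenerate") <- length(bad)
  out
}

#' Orient normals into the +z hemisphere
#'
#' The sign of a fitted plane normal is arbitrary; this fixes it
#' deterministically: flip so that `nz > 0`; if `nz == 0`, so that `ny > 0`;
#' if `ny == 0` too, so that `nx > 0`. Idempotent.
#'
#' @param x A point cloud with `nx`, `ny`, `nz` columns, or an n x 3 matrix
#'   of normals.
#' @return The same type of object with oriented normals.
#' @export
orient_normals <- function(x) {
  if (is.data.frame(x)) {
    if (!has_normals(x)) {
      abort("no nx/ny/nz columns; run compute_normals() first.",
            class = "leafscan_error_input")
    }
    N <- orient_normals(cbind(x$nx, x$ny, x$nz))
    x$nx <- N[, 1]; x$ny <- N[, 2]; x$nz <- N[, 3]
    x
  } else {
    N <- as.matrix(x)
    flip <- N[, 3] < 0 |
      (N[, 3] == 0 & (N[, 2] < 0 | (N[, 2] == 0 & N[, 1] < 0)))
    N[flip, ] <- -N[flip, , drop = FALSE]
    N
  }
}
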