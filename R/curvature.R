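#' Local curvature from normal dispersion
#'
#' For each point, gathers the normals of its `window` x `window`
#' neighbourhood (raster window on organized clouds, `window`^2 nearest
#' neighbours otherwise) and computes
#' `LC = sqrt(s_nx^2 + s_ny^2 + s_nz^2)`, where `s_n*` are the population
#' standard deviations of the normal components over the neighbourhood.
#' Because the normals are unit vectors, the summed variance equals
#' `1 - ||mean normal||^2`, so `LC` is bounded in \[0, 1\]: 0 on a plane
#' (all normals identical), approaching 1 when the neighbourhood's normals
#' are maximally disordered. High LC marks the peaks-and-valleys relief of a
#' blistered leaf; flat lamina scores near 0.
#'
#' Normals must already be oriented consistently (done by
#' [compute_normals()]); unoriented sign flips would inflate the dispersion
#' on smooth surfaces.
#'
#' @param cloud A point cloud with `nx`, `ny`, `nz` columns
#'   (see [compute_normals()]).
#' @param window Odd integer >= 3, points per window side (default 15).
#' @param mode `"auto"`, `"grid"`, or `"knn"`.
#' @return The cloud with columns `lc`, `s_nx`, `s_ny`, `s_nz` added and an
#'   `lc_window` attribute.
#' @export
local_curvature <- function(cloud, window = 15,
                            mode = c("auto", "grid", "knn")) {
  cloud <- as_point_cloud(cloud)
  if (!has_normals(cloud)) {
    abort("no nx/ny/nz columns; run compute_normals() first.",
          class = "leafscan_error_input")
  }
  window <- check_window(window)
  mode <- resolve_mode(cloud, mode)
  n <- nrow(cloud)
  if (mode == "knn" && n < window^2) {
    abort(sprintf(
      "cloud too small: knn curvature with window %d needs >= %d points (%d).",
      window, window^2, n),
      class = "leafscan_error_param")
  }
  nbr <- neighbor_matrix(cloud, window, mode)
  k <- ncol(nbr)
  sds <- matrix(0, nrow = n, ncol = 3)
  for (j in 1:3) {
    v <- list(cloud$nx, cloud$ny, cloud$nz)[[j]]
    vm <- matrix(v[nbr], nrow = n, ncol = k)
    m1 <- rowMeans(vm, na.rm = TRUE)
    m2 <- rowMeans(vm^2, na.rm = TRUE)
    sds[, j] <- sqrt(pmax(0, m2 - m1^2))
  }
  out <- cloud
  out$s_nx <- sds[, 1]; out$s_ny <- sds[, 2]; out$s_nz <- sds[, 3]
  out$lc <- sqrt(sds[, 1]^2 + sds[, 2]^2 + sds[, 3]^2)
  out <- new_point_cloud(as_tibble(out), grid_shape(cloud))
  attr(out, "normals_window") <- attr(cloud, "normals_window")
  attr(out, "normals_mode") <- attr(cloud, "normals_mode")
  attr(out, "lc_window") <- window
  out
}

#' Local-curvature statistic of one normal set
#'
#' The statistic underlying [local_curvature()], applied to an explicit set
#' of unit normals: the root of the summed population variances of the three
#' components, `sqrt(s_nx^2 + s_ny^2 + s_nz^2)`. For unit vectors this
#' equals `sqrt(1 - ||mean normal||^2)` and is bounded in \[0, 1\].
#'
#' @param normals An n x 3 matrix or data frame of unit normals.
#' @return The LC value (scalar).
#' @export
lc_statistic <- function(normals) {
  N <- as.matrix(normals)
  if (ncol(N) != 3 || nrow(N) < 1) {
    abort("`normals` must be an n x 3 matrix.", class = "leafscan_error_input")
  }
  v <- colMeans(N^2) - colMeans(N)^2
  sqrt(sum(pmax(0, v)))
}

lc_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"lc" %in% names(x)) {
      abort("no `lc` column; run local_curvature() first.",
            class = "leafscan_error_input")
    }
    x$lc
  } else {
    as.numeric(x)
  }
}

#' Histogram of local-curvature values
#'
#' Counts LC values into right-open bins of width `bin_width` over \[0, 1\]
#' (default 0.05, i.e. 20 bins); the last bin is closed, and values >= 1 fall
#' into it.
#'
#' @param x A cloud with an `lc` column, or a numeric vector of LC values.
#' @param bin_width Bin width; must divide 1 evenly (default 0.05).
#' @return A tibble of class `lc_histogram` with columns `bin_lo`, `bin_hi`,
#'   `midpoint`, `frequency`, and attribute `n` (total points).
#' @export
lc_histogram <- function(x, bin_width = 0.05) {
  lc <- lc_values(x)
  if (length(lc) == 0) {
    abort("no LC values to bin.", class = "leafscan_error_empty")
  }
  nb <- 1 / bin_width
  if (!isTRUE(all.equal(nb, round(nb))) || bin_width <= 0 || bin_width > 1) {
    abort("`bin_width` must divide 1 evenly.", class = "leafscan_error_param")
  }
  nb <- as.integer(round(nb))
  idx <- pmin(nb - 1L, as.integer(floor(lc / bin_width))) + 1L
  freq <- tabulate(idx, nbins = nb)
  edges <- seq(0, 1, length.out = nb + 1)
  out <- tibble(bin_lo = edges[-(nb + 1)],
                bin_hi = edges[-1],
                midpoint = (edges[-(nb + 1)] + edges[-1]) / 2,
                frequency = freq)
  attr(out, "n") <- length(lc)
  class(out) <- c("lc_histogram", class(out))
  out
}

#' Centroid of an LC histogram
#'
#' The frequency-weighted mean of the histogram's bin midpoints,
#' `LCg = sum(midpoint * frequency) / sum(frequency)`. Higher LCg means the
#' LC distribution is skewed towards large values, i.e. a more blistered
#' surface.
#'
#' @param hist An `lc_histogram` (see [lc_histogram()]).
#' @return The centroid LCg (scalar in \[0, 1\]).
#' @export
histogram_centroid <- function(hist) {
  if (!is.data.frame(hist) ||
      !all(c("midpoint", "frequency") %in% names(hist))) {
    abort("`hist` must be an lc_histogram.", class = "leafscan_error_input")
  }
  total <- sum(hist$frequency)
  if (total < 1) {
    abort("empty histogram.", class = "leafscan_error_empty")
  }
  sum(hist$midpoint * hist$frequency) / total
}

#' Fraction of smooth surface
#'
#' The share of points whose LC is below `threshold` (default 0.5): the
#' heatmap's blue-to-green region, read by eye as the smooth part of a leaf.
#' Used as a proxy for blister size: the larger the flat tops of the
#' blisters, the larger this fraction.
#'
#' @param x A cloud with an `lc` column, or a numeric vector of LC values.
#' @param threshold Smoothness cut-off in (0, 1\] (default 0.5).
#' @return Fraction in \[0, 1\].
#' @export
smooth_fraction <- function(x, threshold = 0.5) {
  lc <- lc_values(x)
  if (length(lc) == 0) {
    abort("no LC values.", class = "leafscan_error_empty")
  }
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1].", class = "leafscan_error_param")
  }
  mean(lc < threshold)
}

#' One-stop curvature summary of a (masked) cloud
#'
#' Runs the full pipeline: optional mask, normal estimation, local curvature,
#' histogram, centroid, smooth fraction. The mask is applied *before* normal
#' estimation so excluded points (midrib, margin) never contaminate the
#' windows.
#'
#' @param cloud A point cloud.
#' @param normals_window Window for [compute_normals()] (default 7).
#' @param lc_window Window for [local_curvature()] (default 15).
#' @param bin_width Histogram bin width (default 0.05).
#' @param threshold Smooth cut-off (default 0.5).
#' @param mask Optional integer vector of 1-based indices.
#' @param mode Neighbourhood mode passed to both stages.
#' @return A one-row tibble: `lcg` (binned histogram centroid), `lc_mean`
#'   (raw mean LC, a diagnostic), `smooth_fraction`, `n`, and a parameter
#'   echo.
#' @export
curvature_summary <- function(cloud, normals_window = 7, lc_window = 15,
                              bin_width = 0.05, threshold = 0.5, mask = NULL,
                              mode = c("auto", "grid", "knn")) {
  cloud <- as_point_cloud(cloud)
  mode <- match.arg(mode)
  if (!is.null(mask)) cloud <- apply_mask(cloud, mask)
  cf <- local_curvature(
    compute_normals(cloud, window = normals_window, mode = mode),
    window = lc_window, mode = mode)
  hist <- lc_histogram(cf, bin_width = bin_width)
  tibble(lcg = histogram_centroid(hist),
         lc_mean = mean(cf$lc),
         smooth_fraction = smooth_fraction(cf, threshold = threshold),
         n = nrow(cf),
         normals_window = as.integer(normals_window),
         lc_window = as.integer(lc_window),
         bin_width = bin_width,
         threshold = threshold)
}
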