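#' Batch trait measurement
#'
#' Runs the full trait pipeline on each input scan and returns one row per
#' scan: dimensional traits (height, major/minor diameter, projected area),
#' the four volume estimators plus compactness, and the curvature summary
#' (LC-histogram centroid, raw mean LC, smooth fraction), with a parameter
#' echo for reproducibility. Per-scan failures are recorded in the `status`
#' column without aborting the batch; rows keep a fixed column order.
#'
#' @param inputs Character vector of cloud file paths (PLY/XYZ), or a
#'   (optionally named) list of point clouds / data frames.
#' @param normals_window,lc_window,bin_width,threshold,mode Passed to
#'   [curvature_summary()].
#' @param voxel_size,cell Passed to [volume_report()] /
#'   [plant_dimensions()].
#' @param ground_z Optional ground height (mm) for [plant_dimensions()].
#' @return A tibble, one row per input.
#' @export
measure <- function(inputs, normals_window = 7, lc_window = 15,
                    bin_width = 0.05, threshold = 0.5,
                    mode = c("auto", "grid", "knn"),
                    voxel_size = 0.5, cell = voxel_size, ground_z = NULL) {
  mode <- match.arg(mode)
  if (is.character(inputs)) {
    ids <- basename(inputs)
    loaders <- lapply(inputs, function(p) function() read_point_cloud(p))
  } else {
    if (is.data.frame(inputs)) inputs <- list(inputs)
    ids <- names(inputs) %||% sprintf("scan_%03d", seq_along(inputs))
    ids[ids == ""] <- sprintf("scan_%03d", which(ids == ""))
    loaders <- lapply(inputs, function(cl) function() as_point_cloud(cl))
  }

  template <- tibble(
    id = NA_character_, n_points = NA_integer_,
    height = NA_real_, major_diameter = NA_real_, minor_diameter = NA_real_,
    projected_area = NA_real_,
    bbox_volume = NA_real_, hull_volume = NA_real_,
    columnar_volume = NA_real_, voxel_volume = NA_real_,
    compactness = NA_real_,
    lcg = NA_real_, lc_mean = NA_real_, smooth_fraction = NA_real_,
    normals_window = as.integer(normals_window),
    lc_window = as.integer(lc_window),
    voxel_size = voxel_size, cell = cell,
    bin_width = bin_width, threshold = threshold,
    status = "ok")

  rows <- vector("list", length(loaders))
  for (i in seq_along(loaders)) {
    row <- template
    row$id <- ids[i]
    res <- tryCatch({
      cloud <- loaders[[i]]()
      dims <- plant_dimensions(cloud, ground_z = ground_z, cell = cell)
      vols <- withCallingHandlers(
        volume_report(cloud, voxel_size = voxel_size, cell = cell),
        warning = function(w) invokeRestart("muffleWarning"))
      curv <- curvature_summary(cloud, normals_window = normals_window,
                                lc_window = lc_window,
                                bin_width = bin_width, threshold = threshold,
                                mode = mode)
      row$n_points <- nrow(cloud)
      row$height <- dims$height
      row$major_diameter <- dims$major_diameter
      row$minor_diameter <- dims$minor_diameter
      row$projected_area <- dims$projected_area
      row$bbox_volume <- vols$bbox_volume
      row$hull_volume <- vols$hull_volume
      row$columnar_volume <- vols$columnar_volume
      row$voxel_volume <- vols$voxel_volume
      row$compactness <- vols$compactness
      row$lcg <- curv$lcg
      row$lc_mean <- curv$lc_mean
      row$smooth_fraction <- curv$smooth_fraction
      row
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  out <- bind_rows(rows)
  if (all(out$status != "ok")) {
    abort("every input failed; see the status column for details.",
          class = "leafscan_error_batch")
  }
  out
}

#' Single-leaf blister report
#'
#' Quantifies the blistering of one leaf lamina: the mask (typically the
#' manually cut-out lamina, excluding margin and midrib) is applied first,
#' then normals, local curvature, the LC histogram with per-bin area
#' percentages, the histogram centroid LCg, and the smooth percentage
#' (share of lamina area with LC below the threshold). Optionally writes an
#' LC-heatmap PLY of the masked lamina.
#'
#' @param cloud The leaf point cloud.
#' @param mask Optional integer vector of 1-based indices (see
#'   [read_mask()]).
#' @param normals_window,lc_window,bin_width,threshold,mode As in
#'   [curvature_summary()].
#' @param heatmap_path Optional output path for the LC-heatmap PLY.
#' @return An object of class `blister_report`: `lcg`, `lc_mean`,
#'   `smooth_percent`, `histogram` (tibble with `frequency` and `percent`),
#'   `params`, `n`, `heatmap_path`. [tidy()] returns the histogram,
#'   [glance()] the one-row summary.
#' @export
blister_report <- function(cloud, mask = NULL, normals_window = 7,
                           lc_window = 15, bin_width = 0.05, threshold = 0.5,
                           mode = c("auto", "grid", "knn"),
                           heatmap_path = NULL) {
  cloud <- as_point_cloud(cloud)
  mode <- match.arg(mode)
  if (!is.null(mask)) cloud <- apply_mask(cloud, mask)
  cf <- local_curvature(
    compute_normals(cloud, window = normals_window, mode = mode),
    window = lc_window, mode = mode)
  hist <- lc_histogram(cf, bin_width = bin_width)
  hist$percent <- 100 * hist$frequency / sum(hist$frequency)
  if (!is.null(heatmap_path)) {
    write_colormapped(cf, cf$lc, mode = "lc_heatmap", path = heatmap_path)
  }
  structure(
    list(lcg = histogram_centroid(hist),
         lc_mean = mean(cf$lc),
         smooth_percent = 100 * smooth_fraction(cf, threshold = threshold),
         histogram = hist,
         n = nrow(cf),
         params = list(normals_window = as.integer(normals_window),
                       lc_window = as.integer(lc_window),
                       bin_width = bin_width, threshold = threshold,
                       mode = mode),
         heatmap_path = heatmap_path),
    class = "blister_report")
}

#' @export
print.blister_report <- function(x, ...) {
  cat(sprintf(
    "Blister report: LCg = %.3f, smooth area (LC < %.2f) = %.1f%%, n = %d\n",
    x$lcg, x$params$threshold, x$smooth_percent, x$n))
  if (!is.null(x$heatmap_path)) {
    cat("  heatmap:", x$heatmap_path, "\n")
  }
  invisible(x)
}

#' @export
tidy.blister_report <- function(x, ...) x$histogram

#' @export
glance.blister_report <- function(x, ...) {
  tibble(lcg = x$lcg, lc_mean = x$lc_mean,
         smooth_percent = x$smooth_percent, n = x$n,
         normals_window = x$params$normals_window,
         lc_window = x$params$lc_window,
         bin_width = x$params$bin_width,
         threshold = x$params$threshold)
}
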