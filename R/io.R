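ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_type_what <- function(type) {
  if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") "ply" else if (ext %in% c("xyz", "txt", "asc")) "xyz"
  else {
    head <- readBin(path, "raw", n = 3L)
    if (identical(rawToChar(head), "ply")) "ply" else "xyz"
  }
}

#' Read a point cloud from PLY or XYZ
#'
#' PLY files may be `ascii` or `binary_little_endian`; the `x`, `y`, `z`
#' vertex properties are required and `red`, `green`, `blue` colours are
#' loaded when present. Unknown vertex properties are ignored. XYZ files are
#' whitespace-delimited text with at least three numeric columns; columns
#' 4--6, when present and within 0--255, are taken as colours. Coordinates
#' are in millimetres.
#'
#' @param path Path to the file.
#' @param format `"ply"`, `"xyz"`, or `"auto"` (by extension, then content).
#' @return A [point_cloud()] tibble, point order preserved.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "leafscan_error_io")
  }
  if (format == "auto") format <- guess_format(path)
  if (format == "ply") read_ply(path) else read_xyz(path)
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_pos <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(hdr_pos) == 0 || hdr_pos == -1L) {
    abort(sprintf("%s: no PLY end_header found.", path),
          class = "leafscan_error_format")
  }
  # body starts after the newline terminating the end_header line
  nl <- hdr_pos + 10L
  while (nl <= length(raw) && raw[nl] != as.raw(10L)) nl <- nl + 1L
  body_start <- nl + 1L
  header <- strsplit(rawToChar(raw[seq_len(hdr_pos - 1L)]), "\r?\n")[[1]]
  if (!identical(header[1], "ply")) {
    abort(sprintf("%s: not a PLY file (missing 'ply' magic).", path),
          class = "leafscan_error_format")
  }

  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) {
    abort(sprintf("%s: missing PLY format line.", path),
          class = "leafscan_error_format")
  }
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    abort(sprintf("%s: unsupported PLY format '%s'.", path, fmt),
          class = "leafscan_error_format")
  }

  # parse elements and their properties, in file order
  elements <- list()
  cur <- NULL
  for (line in header[-1]) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(),
                  list_prop = FALSE)
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$list_prop <- TRUE
      } else {
        cur$types <- c(cur$types, tok[2])
        cur$props <- c(cur$props, tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!"vertex" %in% names(elements)) {
    abort(sprintf("%s: PLY has no vertex element.", path),
          class = "leafscan_error_format")
  }
  vert <- elements$vertex
  if (!all(c("x", "y", "z") %in% vert$props)) {
    abort(sprintf("%s: vertex element lacks x/y/z properties.", path),
          class = "leafscan_error_format")
  }
  if (vert$count < 1) {
    abort(sprintf("%s: PLY has zero vertices.", path),
          class = "leafscan_error_empty")
  }
  if (vert$list_prop) {
    abort(sprintf("%s: list properties on the vertex element are unsupported.",
                  path),
          class = "leafscan_error_format")
  }

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[body_start:length(raw)]), "\r?\n")[[1]]
    offset <- 0L
    for (el in elements) {
      if (el$name == "vertex") break
      offset <- offset + el$count
    }
    lines <- body[(offset + 1L):(offset + vert$count)]
    con <- textConnection(lines)
    on.exit(close(con))
    vals <- tryCatch(scan(con, what = numeric(), quiet = TRUE),
                     error = function(e) {
                       abort(sprintf("%s: malformed ascii vertex data (%s).",
                                     path, conditionMessage(e)),
                             class = "leafscan_error_format")
                     })
    if (length(vals) != vert$count * length(vert$props)) {
      abort(sprintf("%s: expected %d numbers for vertex element, found %d.",
                    path, vert$count * length(vert$props), length(vals)),
            class = "leafscan_error_format")
    }
    m <- matrix(vals, ncol = length(vert$props), byrow = TRUE)
    colnames(m) <- vert$props
  } else {
    pos <- body_start
    for (el in elements) {
      if (el$name == "vertex") break
      if (el$list_prop) {
        abort(sprintf(
          "%s: binary element '%s' with list properties precedes vertex.",
          path, el$name), class = "leafscan_error_format")
      }
      pos <- pos + el$count * sum(ply_type_size[el$types])
    }
    sizes <- ply_type_size[vert$types]
    if (anyNA(sizes)) {
      abort(sprintf("%s: unknown PLY property type.", path),
            class = "leafscan_error_format")
    }
    row_size <- sum(sizes)
    need <- vert$count * row_size
    if (length(raw) - pos + 1L < need) {
      abort(sprintf("%s: binary vertex data truncated.", path),
            class = "leafscan_error_format")
    }
    offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
    m <- matrix(0, nrow = vert$count, ncol = length(vert$props))
    colnames(m) <- vert$props
    row_starts <- pos + (seq_len(vert$count) - 1L) * row_size
    for (j in seq_along(vert$props)) {
      sz <- sizes[j]
      idx <- as.vector(outer(seq_len(sz) - 1L, row_starts + offs[j], `+`))
      m[, j] <- readBin(raw[idx], ply_type_what(vert$types[j]), n = vert$count,
                        size = sz, endian = "little",
                        signed = !(vert$types[j] %in%
                                     c("uchar", "uint8", "ushort", "uint16")))
    }
  }

  df <- tibble(x = m[, "x"], y = m[, "y"], z = m[, "z"])
  if (all(c("red", "green", "blue") %in% vert$props)) {
    df$r <- as.integer(round(m[, "red"]))
    df$g <- as.integer(round(m[, "green"]))
    df$b <- as.integer(round(m[, "blue"]))
  }
  if (all(c("nx", "ny", "nz") %in% vert$props)) {
    df$nx <- m[, "nx"]; df$ny <- m[, "ny"]; df$nz <- m[, "nz"]
  }
  point_cloud(df)
}

read_xyz <- function(path) {
  vals <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) {
      abort(sprintf("%s: malformed XYZ file (%s).", path, conditionMessage(e)),
            class = "leafscan_error_format")
    })
  if (nrow(vals) == 0) {
    abort(sprintf("%s: XYZ file has no points.", path),
          class = "leafscan_error_empty")
  }
  if (ncol(vals) < 3) {
    abort(sprintf("%s: XYZ needs at least 3 numeric columns, found %d.",
                  path, ncol(vals)),
          class = "leafscan_error_format")
  }
  df <- tibble(x = vals[[1]], y = vals[[2]], z = vals[[3]])
  if (ncol(vals) >= 6 &&
      all(vals[[4]] >= 0 & vals[[4]] <= 255) &&
      all(vals[[5]] >= 0 & vals[[5]] <= 255) &&
      all(vals[[6]] >= 0 & vals[[6]] <= 255)) {
    df$r <- as.integer(round(vals[[4]]))
    df$g <- as.integer(round(vals[[5]]))
    df$b <- as.integer(round(vals[[6]]))
  }
  point_cloud(df)
}

#' Write a point cloud to PLY or XYZ
#'
#' PLY is written as `ascii` by default (diffable, byte-deterministic) or as
#' `binary_little_endian`. Colours (`r`, `g`, `b`) and normals
#' (`nx`, `ny`, `nz`) columns are written as the conventional
#' `red/green/blue` uchar and `nx/ny/nz` float vertex properties.
#' Coordinates are written with six decimals (1e-6 mm round-trip).
#'
#' @param cloud A point cloud.
#' @param path Output path.
#' @param format `"ply"`, `"xyz"`, or `"auto"` (by extension).
#' @param binary Write binary little-endian PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyz"),
                              binary = FALSE) {
  cloud <- as_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "xyz") "xyz" else "ply"
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) {
                    abort(sprintf("cannot write to %s", path),
                          class = "leafscan_error_io")
                  })
  on.exit(close(con))
  if (format == "xyz") {
    m <- coords_matrix(cloud)
    lines <- if (has_colors(cloud)) {
      sprintf("%.6f %.6f %.6f %d %d %d", m[, 1], m[, 2], m[, 3],
              cloud$r, cloud$g, cloud$b)
    } else {
      sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3])
    }
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    return(invisible(path))
  }

  n <- nrow(cloud)
  with_rgb <- has_colors(cloud)
  with_nrm <- has_normals(cloud)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment written by leafscan",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (with_nrm) c("property float nx", "property float ny",
                    "property float nz"),
    if (with_rgb) c("property uchar red", "property uchar green",
                    "property uchar blue"),
    "end_header")
  writeLines(header, con, sep = "\n", useBytes = TRUE)

  m <- coords_matrix(cloud)
  if (binary) {
    coord_block <- if (with_nrm) {
      t(cbind(m, cloud$nx, cloud$ny, cloud$nz))
    } else t(m)
    craw <- writeBin(as.vector(coord_block), raw(), size = 4,
                     endian = "little")
    if (with_rgb) {
      ncomp <- nrow(coord_block)
      cmat <- matrix(craw, nrow = 4L * ncomp)
      rgbm <- matrix(as.raw(rbind(cloud$r, cloud$g, cloud$b)), nrow = 3L)
      writeBin(as.vector(rbind(cmat, rgbm)), con)
    } else {
      writeBin(craw, con)
    }
  } else {
    parts <- sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3])
    if (with_nrm) {
      parts <- paste(parts, sprintf("%.8f %.8f %.8f",
                                    cloud$nx, cloud$ny, cloud$nz))
    }
    if (with_rgb) {
      parts <- paste(parts, sprintf("%d %d %d", cloud$r, cloud$g, cloud$b))
    }
    writeLines(parts, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a region mask file
#'
#' Mask files are newline-delimited non-negative 0-based point indices (the
#' convention of the file format); the returned vector is converted to
#' 1-based R indices for use with [apply_mask()].
#'
#' @param path Path to the mask file.
#' @return Integer vector of 1-based indices.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "leafscan_error_io")
  }
  vals <- scan(path, what = integer(), quiet = TRUE)
  if (length(vals) == 0) {
    abort(sprintf("%s: empty mask.", path), class = "leafscan_error_empty")
  }
  if (any(vals < 0)) {
    abort(sprintf("%s: mask indices must be non-negative (0-based).", path),
          class = "leafscan_error_format")
  }
  as.integer(vals) + 1L
}

#' Write a region mask file (0-based indices)
#'
#' @param mask Integer vector of 1-based R indices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(as.integer(mask) - 1L), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

# fixed 256-step blue -> green -> yellow -> red ramp, anchored at 0 and 1
# so colours are comparable across plants
lc_ramp_matrix <- function() {
  ramp <- grDevices::colorRamp(c("blue", "green", "yellow", "red"),
                               space = "rgb")
  round(ramp(seq(0, 1, length.out = 256)))
}

#' Map local-curvature values to the fixed heatmap ramp
#'
#' @param values Numeric values in \[0, 1\]; values outside are clamped with a
#'   warning.
#' @return An n x 3 integer matrix of RGB colours in 0--255.
#' @export
lc_colors <- function(values) {
  values <- as.numeric(values)
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    warn("local-curvature values outside [0, 1] were clamped.")
    values <- pmin(pmax(values, 0), 1)
  }
  ramp <- lc_ramp_matrix()
  idx <- pmin(255L, as.integer(floor(values * 256))) + 1L
  m <- ramp[idx, , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("r", "g", "b")
  m
}

#' Export a colour-mapped point cloud for visualisation
#'
#' `mode = "lc_heatmap"` colours each point by a scalar in \[0, 1\] on a fixed
#' 256-step blue-green-yellow-red ramp (0 = blue, 1 = red; not rescaled to the
#' data, so colours are comparable across plants). `mode = "normal_rgb"`
#' colours each point by its unit normal as
#' (|nx|, |ny|, |nz|) * 255 -> (R, G, B), so an upward-facing surface renders
#' pure blue.
#'
#' @param cloud A point cloud.
#' @param values For `lc_heatmap`, a numeric vector (one value per point).
#'   For `normal_rgb`, an n x 3 matrix/data frame of unit normals, or `NULL`
#'   to use the cloud's `nx`, `ny`, `nz` columns.
#' @param mode `"lc_heatmap"` or `"normal_rgb"`.
#' @param path Output PLY path.
#' @param binary Write binary PLY.
#' @return `path`, invisibly.
#' @export
write_colormapped <- function(cloud, values = NULL,
                              mode = c("lc_heatmap", "normal_rgb"),
                              path, binary = FALSE) {
  cloud <- as_point_cloud(cloud)
  mode <- match.arg(mode)
  n <- nrow(cloud)
  if (mode == "lc_heatmap") {
    if (is.null(values) && "lc" %in% names(cloud)) values <- cloud$lc
    if (is.null(values)) {
      abort("lc_heatmap needs `values` (or an `lc` column).",
            class = "leafscan_error_input")
    }
    values <- as.numeric(values)
    if (length(values) != n) {
      abort(sprintf("length(values) == %d but the cloud has %d points.",
                    length(values), n),
            class = "leafscan_error_input")
    }
    rgb <- lc_colors(values)
  } else {
    if (is.null(values)) {
      if (!has_normals(cloud)) {
        abort("normal_rgb needs `values` (or nx/ny/nz columns).",
              class = "leafscan_error_input")
      }
      values <- cbind(cloud$nx, cloud$ny, cloud$nz)
    }
    values <- as.matrix(values)
    if (nrow(values) != n || ncol(values) != 3) {
      abort("normal_rgb `values` must be an n x 3 matrix of unit normals.",
            class = "leafscan_error_input")
    }
    rgb <- matrix(as.integer(round(255 * pmin(abs(values), 1))), ncol = 3)
    colnames(rgb) <- c("r", "g", "b")
  }
  out <- as_tibble(as.data.frame(cloud)[, c("x", "y", "z")])
  out$r <- rgb[, 1]; out$g <- rgb[, 2]; out$b <- rgb[, 3]
  write_point_cloud(new_point_cloud(out, grid_shape(cloud)), path,
                    format = "ply", binary = binary)
}
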