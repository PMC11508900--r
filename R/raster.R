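#' Gridded raster layers on a geographic (WGS84) grid
#'
#' `raster_grid()` builds the package's in-memory raster container: a
#' north-up rectangular grid of square cells in decimal degrees, row 0 at
#' the top, with `NA` cells treated as NoData. The cell at (row `r`,
#' column `c`), both 0-based, has its centre at
#' `(x_min + (c + 0.5) * cell_size, y_max - (r + 0.5) * cell_size)`.
#'
#' @param values numeric matrix of cell values; `NA` marks NoData cells.
#' @param x_min western edge (degrees longitude) of the grid.
#' @param y_max northern edge (degrees latitude) of the grid.
#' @param cell_size cell edge length in degrees (cells are square).
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), x_min = 100, y_max = 40, cell_size = 0.5)
#' dim(g)
#' @export
raster_grid <- function(values, x_min, y_max, cell_size) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "ensdm_format_error")
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort("raster must have at least one row and column.", class = "ensdm_format_error")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a single positive number.", class = "ensdm_format_error")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort("non-finite, non-NA cell values are not allowed.", class = "ensdm_format_error")
  }
  structure(
    list(values = unname(values), x_min = as.numeric(x_min),
         y_max = as.numeric(y_max), cell_size = as.numeric(cell_size)),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  n_nodata <- sum(is.na(x$values))
  cat(sprintf("<raster_grid> %d x %d cells, cell size %g deg\n", d[1], d[2], x$cell_size))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$x_min, x$x_min + d[2] * x$cell_size,
              x$y_max - d[1] * x$cell_size, x$y_max))
  cat(sprintf("  NoData cells: %d / %d\n", n_nodata, length(x$values)))
  if (any(!is.na(x$values))) {
    cat(sprintf("  value range: [%g, %g]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

# Geometry descriptor used in alignment error messages.
grid_geometry <- function(g) {
  sprintf("%dx%d @ %.10g deg, origin (%.10g, %.10g)",
          nrow(g$values), ncol(g$values), g$cell_size, g$x_min, g$y_max)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$x_min, b$x_min, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$y_max, b$y_max, tolerance = 1e-12))
}

#' Cell centre coordinates
#'
#' @param grid a [raster_grid].
#' @param row,col 0-based row/column indices (vectors recycled together).
#' @return tibble with `longitude` and `latitude` of cell centres.
#' @export
cell_center <- function(grid, row, col) {
  tibble(
    longitude = grid$x_min + (col + 0.5) * grid$cell_size,
    latitude  = grid$y_max - (row + 0.5) * grid$cell_size
  )
}

# Map lon/lat to 0-based (row, col); half-open cells: a point on a cell's
# right or bottom edge belongs to the next cell. Returns NA for points
# outside the grid bounds.
cell_of <- function(grid, longitude, latitude) {
  d <- dim(grid$values)
  col <- floor((longitude - grid$x_min) / grid$cell_size)
  row <- floor((grid$y_max - latitude) / grid$cell_size)
  outside <- col < 0 | col >= d[2] | row < 0 | row >= d[1] |
    !is.finite(longitude) | !is.finite(latitude)
  row[outside] <- NA_real_
  col[outside] <- NA_real_
  list(row = row, col = col)
}

#' Convert a raster to a per-cell tibble
#'
#' One row per cell, with 0-based `row`/`col`, centre coordinates and the
#' cell value (`NA` where NoData).
#' @param x a [raster_grid].
#' @param ... unused.
#' @exportS3Method tibble::as_tibble
as_tibble.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  rows <- rep(seq_len(d[1]) - 1L, times = d[2])
  cols <- rep(seq_len(d[2]) - 1L, each = d[1])
  ctr <- cell_center(x, rows, cols)
  tibble(row = rows, col = cols,
         longitude = ctr$longitude, latitude = ctr$latitude,
         value = as.vector(x$values))
}

#' Read a single-band raster
#'
#' Reads an ESRI ASCII grid (`.asc`: `ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by row-major
#' values, northernmost row first). The GeoTIFF dialect is declared for
#' interface completeness but is not available in this build.
#'
#' @param path file to read.
#' @param dialect raster format; only `"ascii_grid"` is supported.
#' @return a [raster_grid]; NoData values become `NA` cells.
#' @export
read_raster <- function(path, dialect = c("ascii_grid", "geotiff")) {
  dialect <- match.arg(dialect)
  if (dialect == "geotiff") {
    abort("the GeoTIFF dialect is not supported by this build; use ESRI ASCII grids.",
          class = "ensdm_format_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("raster file not found: %s", path), class = "ensdm_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  hdr_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c(hdr_keys, "dx", "dy"))) break
    val <- suppressWarnings(as.numeric(parts[2]))
    if (length(parts) != 2 || is.na(val)) {
      abort(sprintf("malformed ASCII grid header field '%s' in %s", parts[1], path),
            class = "ensdm_format_error")
    }
    hdr[[key]] <- val
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner")) {
    if (is.null(hdr[[k]])) {
      abort(sprintf("ASCII grid header missing required field '%s' in %s", k, path),
            class = "ensdm_format_error")
    }
  }
  if (is.null(hdr$cellsize)) {
    if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
      if (!isTRUE(all.equal(hdr$dx, hdr$dy))) {
        abort(sprintf("non-square cells (dx=%g, dy=%g) are unsupported in %s",
                      hdr$dx, hdr$dy, path),
              class = "ensdm_geometry_error")
      }
      hdr$cellsize <- hdr$dx
    } else {
      abort(sprintf("ASCII grid header missing required field 'cellsize' in %s", path),
            class = "ensdm_format_error")
    }
  }
  nodata <- hdr$nodata_value %||% -9999
  body <- lines[i:length(lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  n_expect <- hdr$ncols * hdr$nrows
  if (length(vals) != n_expect || anyNA(vals)) {
    abort(sprintf(
      "ASCII grid body of %s does not match header: expected %d numeric values (ncols=%d x nrows=%d), found %d",
      path, n_expect, hdr$ncols, hdr$nrows, length(vals)),
      class = "ensdm_format_error")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, x_min = hdr$xllcorner,
              y_max = hdr$yllcorner + hdr$nrows * hdr$cellsize,
              cell_size = hdr$cellsize)
}

#' Write a raster to disk
#'
#' Writes an ESRI ASCII grid; NoData cells are written as the sentinel
#' value (default -9999). Values are written with 17 significant digits so
#' a write/read round trip reproduces doubles exactly.
#'
#' @param grid a [raster_grid].
#' @param path output file.
#' @param dialect only `"ascii_grid"` is supported.
#' @param nodata NoData sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, dialect = c("ascii_grid", "geotiff"),
                         nodata = -9999) {
  dialect <- match.arg(dialect)
  if (dialect == "geotiff") {
    abort("the GeoTIFF dialect is not supported by this build; use ESRI ASCII grids.",
          class = "ensdm_format_error")
  }
  d <- dim(grid$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.17g", grid$x_min),
    sprintf("yllcorner %.17g", grid$y_max - d[1] * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata)
  )
  m <- grid$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Stack aligned environmental layers
#'
#' Verifies that all layers share an identical grid geometry (no resampling
#' is ever performed — mismatches are treated as data errors) and computes
#' the shared NoData mask as the union of the per-layer masks. All
#' downstream extraction reads only cells clear in the shared mask.
#'
#' @param layers list of [raster_grid] objects.
#' @param names character vector of unique layer names; defaults to
#'   `names(layers)`.
#' @return an object of class `env_stack`.
#' @export
align_stack <- function(layers, names = NULL) {
  if (length(layers) < 1) {
    abort("at least one layer is required.", class = "ensdm_alignment_error")
  }
  names <- names %||% base::names(layers)
  if (is.null(names) || length(names) != length(layers) || anyDuplicated(names)) {
    abort("layers need unique names.", class = "ensdm_alignment_error")
  }
  ref <- layers[[1]]
  for (j in seq_along(layers)) {
    if (!inherits(layers[[j]], "raster_grid")) {
      abort("all layers must be raster_grid objects.", class = "ensdm_alignment_error")
    }
    if (!same_geometry(ref, layers[[j]])) {
      abort(sprintf("layer '%s' [%s] does not align with layer '%s' [%s]",
                    names[j], grid_geometry(layers[[j]]),
                    names[1], grid_geometry(ref)),
            class = "ensdm_alignment_error")
    }
  }
  mask <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  structure(
    list(layers = stats::setNames(layers, names), layer_names = names,
         shared_mask = mask),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers: %s\n", length(x$layers),
              paste(x$layer_names, collapse = ", ")))
  cat(sprintf("  geometry: %s\n", grid_geometry(x$layers[[1]])))
  cat(sprintf("  shared NoData cells: %d / %d\n", sum(x$shared_mask), length(x$shared_mask)))
  invisible(x)
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1]]$values)

# Covariate tibble of all cells clear in the shared mask, with 0-based
# row/col. Used for projection and response curves.
stack_cell_table <- function(stack) {
  d <- dim(stack)
  keep <- !as.vector(stack$shared_mask)
  rows <- rep(seq_len(d[1]) - 1L, times = d[2])[keep]
  cols <- rep(seq_len(d[2]) - 1L, each = d[1])[keep]
  vals <- lapply(stack$layers, function(g) as.vector(g$values)[keep])
  dplyr::bind_cols(tibble(row = rows, col = cols), as_tibble(vals))
}

#' Slope and aspect from elevation (Horn's method)
#'
#' Computes per-cell slope (degrees from horizontal) and aspect (degrees
#' clockwise from north, in `[0, 360)`) from the 3x3 neighbourhood using
#' Horn's weighted finite differences — the default algorithm of standard
#' GIS software. Horizontal distances are converted from degrees to metres
#' at each cell's latitude (111320 m per degree latitude; `111320 * cos(lat)`
#' per degree longitude) so slopes are physically meaningful. Border cells
#' and cells with any NoData neighbour are NoData in the output; flat cells
#' (zero gradient) get the aspect sentinel `-1`.
#'
#' @param elevation a [raster_grid] of elevation in metres.
#' @return list with elements `slope` and `aspect`, both [raster_grid].
#' @export
derive_terrain <- function(elevation) {
  z <- elevation$values
  d <- dim(z)
  if (d[1] < 3 || d[2] < 3) {
    abort("terrain derivation needs at least a 3x3 grid with an interior cell.",
          class = "ensdm_empty_error")
  }
  # shifted views of the 3x3 neighbourhood of each interior cell:
  #   a b c
  #   d e f     (a is the north-west neighbour)
  #   g h i
  ri <- 2:(d[1] - 1); ci <- 2:(d[2] - 1)
  a <- z[ri - 1, ci - 1, drop = FALSE]; b <- z[ri - 1, ci, drop = FALSE]; cc <- z[ri - 1, ci + 1, drop = FALSE]
  dd <- z[ri, ci - 1, drop = FALSE];                                     f <- z[ri, ci + 1, drop = FALSE]
  g <- z[ri + 1, ci - 1, drop = FALSE]; h <- z[ri + 1, ci, drop = FALSE]; ii <- z[ri + 1, ci + 1, drop = FALSE]

  lat <- elevation$y_max - (ri - 0.5) * elevation$cell_size
  mx <- 111320 * cos(lat * pi / 180) * elevation$cell_size  # metres per cell, east-west
  my <- 111320 * elevation$cell_size                        # metres per cell, north-south

  dzdx <- ((cc + 2 * f + ii) - (a + 2 * dd + g)) / (8 * mx)  # recycled by row
  dzdy <- ((g + 2 * h + ii) - (a + 2 * b + cc)) / (8 * my)

  slope_deg <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  asp_math <- atan2(dzdy, -dzdx) * 180 / pi
  aspect <- 90 - asp_math
  aspect <- aspect %% 360
  flat <- is.finite(dzdx) & is.finite(dzdy) & dzdx == 0 & dzdy == 0
  aspect[flat] <- -1

  slope_full <- matrix(NA_real_, d[1], d[2])
  aspect_full <- matrix(NA_real_, d[1], d[2])
  slope_full[ri, ci] <- slope_deg
  aspect_full[ri, ci] <- aspect
  if (all(is.na(slope_full))) {
    abort("terrain derivation produced no valid cells (input all NoData?).",
          class = "ensdm_empty_error")
  }
  list(
    slope = raster_grid(slope_full, elevation$x_min, elevation$y_max, elevation$cell_size),
    aspect = raster_grid(aspect_full, elevation$x_min, elevation$y_max, elevation$cell_size)
  )
}

#' Extract covariate values at point locations
#'
#' Maps each point to its containing cell (half-open cells; a point on a
#' cell's right or bottom edge belongs to the next cell) and reads every
#' layer. Points outside the grid or in shared-mask cells are returned
#' flagged in the `status` column (`"outside"` / `"nodata"`), never
#' silently dropped.
#'
#' @param stack an [align_stack] result.
#' @param points data frame with `longitude` and `latitude` columns.
#' @return tibble: the input coordinates, `status`, 0-based `row`/`col`,
#'   and one column per layer (NA where flagged).
#' @export
extract_values <- function(stack, points) {
  if (nrow(points) < 1) {
    abort("`points` must contain at least one point.", class = "ensdm_empty_error")
  }
  ref <- stack$layers[[1]]
  cl <- cell_of(ref, points$longitude, points$latitude)
  n <- nrow(points)
  status <- rep("ok", n)
  status[is.na(cl$row)] <- "outside"
  inside <- status == "ok"
  idx <- cl$row[inside] + 1 + cl$col[inside] * nrow(ref$values)
  masked <- as.vector(stack$shared_mask)[idx]
  status[which(inside)[masked]] <- "nodata"
  ok <- status == "ok"
  out <- tibble(longitude = points$longitude, latitude = points$latitude,
                status = status, row = cl$row, col = cl$col)
  for (nm in stack$layer_names) {
    v <- rep(NA_real_, n)
    v[inside] <- as.vector(stack$layers[[nm]]$values)[idx]
    v[!ok] <- NA_real_
    out[[nm]] <- v
  }
  out
}

#' Geodesic cell areas for a raster row
#'
#' Area in km^2 of each cell in the given 0-based row(s), by the spherical
#' formula `R^2 * dlambda * (sin(lat_top) - sin(lat_bottom))` with
#' `R = 6371.0088` km. Constant across columns within a row.
#'
#' @param grid a [raster_grid] (only the geometry is used).
#' @param row 0-based row index (vectorised).
#' @return numeric vector of per-cell areas (km^2), one per input row.
#' @export
cell_area <- function(grid, row) {
  to_rad <- pi / 180
  lat_top <- (grid$y_max - row * grid$cell_size) * to_rad
  lat_bot <- (grid$y_max - (row + 1) * grid$cell_size) * to_rad
  dl <- grid$cell_size * to_rad
  EARTH_RADIUS_KM^2 * dl * (sin(lat_top) - sin(lat_bot))
}
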