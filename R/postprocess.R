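#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming partition of 1-D values into `k` classes
#' minimising the total within-class sum of squared deviations from the
#' class means. Returns the `k - 1` boundary values, each the maximum
#' member of its (lower) class, in ascending order. For very many distinct
#' values the input is first condensed onto `max_bins` weighted quantile
#' bins (the optimisation is then exact on the binned values); below that
#' size the computation is exact on the raw values.
#'
#' @param values numeric vector (e.g. suitability of unmasked cells).
#' @param k number of classes (default 4).
#' @param max_bins condensation limit for the exact DP (default 2048).
#' @return numeric vector of `k - 1` ascending break values.
#' @export
jenks_breaks <- function(values, k = 4, max_bins = 2048) {
  values <- values[!is.na(values)]
  ux <- sort(unique(values))
  if (length(ux) < k) {
    abort(sprintf("need at least %d distinct values for %d classes (have %d).",
                  k, k, length(ux)), class = "ensdm_classification_error")
  }
  if (length(ux) > max_bins) {
    # condense to weighted quantile bins; DP stays exact on the binned data
    edges <- unique(interp_quantile(values, seq(0, 1, length.out = max_bins + 1)))
    bin <- findInterval(values, edges, rightmost.closed = TRUE)
    agg <- tapply(values, bin, mean)
    w <- as.numeric(table(bin))
    ux <- as.numeric(agg)
    ord <- order(ux)
    ux <- ux[ord]; w <- w[ord]
  } else {
    w <- as.numeric(table(match(values, ux)))
  }
  n <- length(ux)
  cw <- cumsum(w)
  cwx <- cumsum(w * ux)
  cwx2 <- cumsum(w * ux^2)
  # weighted SSD of values a..b (1-based, inclusive)
  ssd <- function(a, b) {
    sw <- cw[b] - if (a > 1) cw[a - 1] else 0
    sx <- cwx[b] - if (a > 1) cwx[a - 1] else 0
    sx2 <- cwx2[b] - if (a > 1) cwx2[a - 1] else 0
    pmax(0, sx2 - sx^2 / sw)
  }
  D <- matrix(Inf, n, k)
  B <- matrix(0L, n, k)
  D[, 1] <- vapply(seq_len(n), function(i) ssd(1, i), numeric(1))
  for (j in 2:k) {
    for (i in j:n) {
      m <- (j - 1):(i - 1)
      sw <- cw[i] - cw[m]
      sx <- cwx[i] - cwx[m]
      sx2 <- cwx2[i] - cwx2[m]
      cost <- D[m, j - 1] + pmax(0, sx2 - sx^2 / sw)
      best <- which.min(cost)
      D[i, j] <- cost[best]
      B[i, j] <- m[best]
    }
  }
  # backtrack class upper edges
  breaks <- numeric(k - 1)
  i <- n
  for (j in k:2) {
    m <- B[i, j]
    breaks[j - 1] <- ux[m]
    i <- m
  }
  breaks
}

#' Classify a suitability map at fixed breaks
#'
#' Cell class = number of break points strictly below the cell's value
#' (values equal to a break fall in the lower class): with three breaks
#' the classes are 0 = no suitability, 1 = low, 2 = medium, 3 = high.
#' Class areas are accumulated with the geodesic [cell_area] model.
#'
#' @param suitability a [raster_grid].
#' @param break_points ascending numeric thresholds (typically
#'   [jenks_breaks] output).
#' @return object of class `classified_map`: list with `grid` (class
#'   codes), `break_points` and `class_areas` (tibble `class`,
#'   `area_km2`).
#' @export
classify_map <- function(suitability, break_points) {
  if (is.unsorted(break_points, strictly = TRUE)) {
    abort("`break_points` must be strictly ascending.", class = "ensdm_parameter_error")
  }
  v <- suitability$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  counts <- rep(0, sum(ok))
  for (b in break_points) counts <- counts + (v[ok] > b)
  cls[ok] <- counts
  grid <- raster_grid(cls, suitability$x_min, suitability$y_max, suitability$cell_size)
  tb <- as_tibble(grid)
  tb <- tb[!is.na(tb$value), ]
  tb$area <- cell_area(grid, tb$row)
  areas <- tb |>
    dplyr::group_by(class = .data$value) |>
    dplyr::summarise(area_km2 = sum(.data$area), .groups = "drop") |>
    dplyr::right_join(tibble(class = 0:length(break_points)), by = "class") |>
    dplyr::mutate(area_km2 = ifelse(is.na(.data$area_km2), 0, .data$area_km2)) |>
    dplyr::arrange(.data$class)
  structure(list(grid = grid, break_points = break_points, class_areas = areas),
            class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  cat(sprintf("<classified_map> %d classes, breaks: %s\n",
              length(x$break_points) + 1,
              paste(signif(x$break_points, 5), collapse = ", ")))
  print(x$class_areas)
  invisible(x)
}

#' Standard land-use legend
#'
#' The nine land-cover categories used by the land-use overlay, with their
#' integer raster codes.
#' @return tibble: `code`, `label`.
#' @export
landuse_legend <- function() {
  tibble(code = 1:9,
         label = c("grassland", "barren", "forest", "cropland", "water",
                   "shrubs", "ice_snow", "wetland", "impervious"))
}

#' Cross-tabulate habitat classes against land use
#'
#' Exact per-cell cross-tabulation of suitability class x land-use
#' category, with areas from [cell_area]. Cells NoData in either layer are
#' excluded from both margins.
#'
#' @param classified a [classify_map] result.
#' @param landuse [raster_grid] of integer category codes, aligned with
#'   the classified grid.
#' @param legend tibble with `code`/`label` (default [landuse_legend]).
#' @return tibble of class `landuse_cross`: `landuse`, `suitability_class`,
#'   `area_km2`.
#' @export
crosstab_landuse <- function(classified, landuse, legend = landuse_legend()) {
  g <- classified$grid
  if (!same_geometry(g, landuse)) {
    abort(sprintf("land-use grid [%s] does not align with classified grid [%s]",
                  grid_geometry(landuse), grid_geometry(g)),
          class = "ensdm_alignment_error")
  }
  cls <- as.vector(g$values)
  lu <- as.vector(landuse$values)
  ok <- !is.na(cls) & !is.na(lu)
  if (!any(ok)) {
    warn("classified map and land-use masks are disjoint; empty cross-tabulation.")
    return(structure(tibble(landuse = character(), suitability_class = numeric(),
                            area_km2 = numeric()), class = c("landuse_cross", "tbl_df", "tbl", "data.frame")))
  }
  d <- dim(g$values)
  rows <- rep(seq_len(d[1]) - 1L, times = d[2])
  area <- cell_area(g, rows)
  tb <- tibble(code = lu[ok], suitability_class = cls[ok], area = area[ok]) |>
    dplyr::group_by(.data$code, .data$suitability_class) |>
    dplyr::summarise(area_km2 = sum(.data$area), .groups = "drop") |>
    dplyr::left_join(legend, by = "code") |>
    dplyr::mutate(landuse = ifelse(is.na(.data$label), paste0("class_", .data$code),
                                   .data$label)) |>
    dplyr::select("landuse", "suitability_class", "area_km2")
  class(tb) <- c("landuse_cross", class(tb))
  tb
}

#' Per-tile samples of land-use and suitable-habitat area
#'
#' Splits the study area into regular `tile_size` x `tile_size` cell
#' tiles; each tile contributes, per land-use class, one (land-use area,
#' suitable-habitat area) pair, where suitable habitat pools classes >= 1
#' (the suitable/unsuitable dichotomy). These spatial-unit samples feed
#' [landuse_correlation].
#'
#' @param classified a [classify_map] result.
#' @param landuse aligned land-use [raster_grid].
#' @param tile_size tile edge in cells (default 10).
#' @param legend tibble with `code`/`label`.
#' @return tibble: `tile`, `landuse`, `landuse_area_km2`,
#'   `suitable_area_km2`.
#' @export
tile_landuse_samples <- function(classified, landuse, tile_size = 10,
                                 legend = landuse_legend()) {
  g <- classified$grid
  if (!same_geometry(g, landuse)) {
    abort("land-use grid does not align with the classified grid.",
          class = "ensdm_alignment_error")
  }
  d <- dim(g$values)
  rows <- rep(seq_len(d[1]) - 1L, times = d[2])
  cols <- rep(seq_len(d[2]) - 1L, each = d[1])
  tile <- (rows %/% tile_size) * 1000L + (cols %/% tile_size)
  cls <- as.vector(g$values)
  lu <- as.vector(landuse$values)
  area <- cell_area(g, rows)
  ok <- !is.na(cls) & !is.na(lu)
  df <- tibble(tile = tile[ok], code = lu[ok], suitable = cls[ok] >= 1,
               area = area[ok])
  suit_by_tile <- df |>
    dplyr::group_by(.data$tile) |>
    dplyr::summarise(suitable_area_km2 = sum(.data$area[.data$suitable]),
                     .groups = "drop")
  lu_by_tile <- df |>
    dplyr::group_by(.data$tile, .data$code) |>
    dplyr::summarise(landuse_area_km2 = sum(.data$area), .groups = "drop") |>
    tidyr::complete(tile = unique(df$tile), code = legend$code,
                    fill = list(landuse_area_km2 = 0))
  lu_by_tile |>
    dplyr::left_join(legend, by = "code") |>
    dplyr::left_join(suit_by_tile, by = "tile") |>
    dplyr::transmute(tile = .data$tile, landuse = .data$label,
                     landuse_area_km2 = .data$landuse_area_km2,
                     suitable_area_km2 = .data$suitable_area_km2)
}

#' Correlation of suitable-habitat area with land-use area
#'
#' Per land-use class, an ordinary-least-squares fit of suitable-habitat
#' area on land-use area over spatial units, with Pearson r, the
#' coefficient of determination `R^2 = 1 - SSres / SStot`, and the
#' two-sided p-value from the t distribution with `n - 2` degrees of
#' freedom. Classes whose land-use area does not vary across units are
#' reported degenerate (`NA` statistics) rather than failing the whole
#' analysis.
#'
#' @param samples tibble from [tile_landuse_samples] (columns `landuse`,
#'   `landuse_area_km2`, `suitable_area_km2`).
#' @return tibble: `landuse`, `n`, `pearson_r`, `r_squared`, `p_value`,
#'   `slope`, `intercept`, `degenerate`.
#' @export
landuse_correlation <- function(samples) {
  if (nrow(samples) < 3) {
    abort("need at least 3 spatial units.", class = "ensdm_data_error")
  }
  samples |>
    dplyr::group_by(.data$landuse) |>
    dplyr::group_modify(function(df, key) {
      x <- df$landuse_area_km2; y <- df$suitable_area_km2
      n <- length(x)
      if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
        return(tibble(n = n, pearson_r = NA_real_, r_squared = NA_real_,
                      p_value = NA_real_, slope = NA_real_,
                      intercept = NA_real_, degenerate = TRUE))
      }
      fit <- stats::lm(y ~ x)
      ss_res <- sum(stats::residuals(fit)^2)
      ss_tot <- sum((y - mean(y))^2)
      r <- stats::cor(x, y)
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
      tibble(n = n, pearson_r = r, r_squared = 1 - ss_res / ss_tot,
             p_value = p, slope = stats::coef(fit)[[2]],
             intercept = stats::coef(fit)[[1]], degenerate = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Distribution centre of a binary range map
#'
#' Area-weighted mean of the presence-cell centre coordinates (weights =
#' geodesic cell areas); longitudes are averaged arithmetically, which is
#' valid for study areas spanning well under 180 degrees.
#'
#' @param binary [raster_grid] with values in `{0, 1}`.
#' @return tibble with one row: `longitude`, `latitude`, `n_cells`,
#'   `area_km2`.
#' @export
distribution_center <- function(binary) {
  tb <- as_tibble(binary)
  pres <- tb[!is.na(tb$value) & tb$value == 1, ]
  if (nrow(pres) == 0) {
    abort("binary map has no presence cells.", class = "ensdm_empty_error")
  }
  w <- cell_area(binary, pres$row)
  tibble(longitude = sum(w * pres$longitude) / sum(w),
         latitude = sum(w * pres$latitude) / sum(w),
         n_cells = nrow(pres), area_km2 = sum(w))
}

#' Track distribution-centre shifts across periods
#'
#' Computes the distribution centre of each period's binary map, then the
#' great-circle (haversine, R = 6371.0088 km) distance and forward azimuth
#' of each consecutive step.
#'
#' @param binary_maps named list of binary [raster_grid]s, in period
#'   order.
#' @param periods period labels (default `names(binary_maps)`).
#' @return object of class `centroid_track`: list with `centers` (tibble
#'   `period`, `longitude`, `latitude`, `area_km2`) and `steps` (tibble
#'   `from`, `to`, `distance_km`, `bearing_deg`).
#' @export
centroid_track <- function(binary_maps, periods = NULL) {
  periods <- periods %||% names(binary_maps)
  if (length(binary_maps) < 2) {
    abort("need at least 2 periods.", class = "ensdm_parameter_error")
  }
  centers <- purrr::map2_dfr(binary_maps, periods, function(bm, p) {
    ctr <- tryCatch(distribution_center(bm), error = function(e) {
      abort(sprintf("period '%s': %s", p, conditionMessage(e)),
            class = "ensdm_empty_error")
    })
    dplyr::mutate(ctr, period = p, .before = 1)
  })
  from <- centers[-nrow(centers), ]
  to <- centers[-1, ]
  p1 <- cbind(from$longitude, from$latitude)
  p2 <- cbind(to$longitude, to$latitude)
  steps <- tibble(
    from = from$period, to = to$period,
    distance_km = geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000,
    bearing_deg = geosphere::bearing(p1, p2) %% 360
  )
  structure(list(centers = centers, steps = steps), class = "centroid_track")
}

#' @export
print.centroid_track <- function(x, ...) {
  cat(sprintf("<centroid_track> %d periods\n", nrow(x$centers)))
  print(x$centers)
  print(x$steps)
  invisible(x)
}
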