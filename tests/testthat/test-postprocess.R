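test_that("jenks breaks reproduce hand-checked partitions", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2), 3)
  # k distinct values in k classes: zero within-class SSD
  v <- c(2, 7, 9, 20)
  br <- jenks_breaks(v, k = 4)
  expect_equal(breaks_ssd(v, br), 0)
  expect_error(jenks_breaks(rep(1, 4), k = 4), class = "ensdm_classification_error")
})

test_that("jenks equals exhaustive enumeration on small instances", {
  withr::with_seed(77, {
    for (i in 1:30) {
      n <- sample(5:14, 1)
      k <- sample(2:4, 1)
      v <- round(stats::runif(n, 0, 10), 2)
      if (length(unique(v)) < k) next
      br <- jenks_breaks(v, k)
      expect_equal(breaks_ssd(v, br), oracle_jenks_ssd(v, k), tolerance = 1e-9)
      expect_equal(length(br), k - 1)
      expect_false(is.unsorted(br, strictly = TRUE))
    }
  })
})

test_that("binned large-n jenks stays close to the exact optimum", {
  withr::with_seed(5, v <- c(stats::rnorm(3000, 0), stats::rnorm(3000, 6)))
  br_exact <- jenks_breaks(v, k = 2)               # ~6000 unique <= 2048? no: binned
  br_small <- jenks_breaks(v, k = 2, max_bins = 10000)  # exact
  expect_equal(br_exact, br_small, tolerance = 0.05)
})

test_that("classification uses the strictly-below-break convention", {
  g <- raster_grid(matrix(c(0.1, 0.5, 0.6, 0.9), 2, 2), 100, 40, 0.5)
  cm <- classify_map(g, c(0.25, 0.5, 0.75))
  expect_equal(cm$grid$values[1, 1], 0)
  expect_equal(cm$grid$values[2, 1], 1)  # 0.5 == break: lower class
  expect_equal(cm$grid$values[1, 2], 2)
  expect_equal(cm$grid$values[2, 2], 3)
  expect_error(classify_map(g, c(0.5, 0.25)), class = "ensdm_parameter_error")

  # checkerboard splits evenly between extreme classes
  cb <- raster_grid(matrix(rep(c(0.1, 0.9), 8), 4, 4), 100, 40, 0.5)
  cmc <- classify_map(cb, c(0.25, 0.5, 0.75))
  expect_equal(sum(cmc$grid$values == 0), 8)
  expect_equal(sum(cmc$grid$values == 3), 8)
})

test_that("raising a cell's suitability never lowers its class", {
  withr::with_seed(11, {
    v <- matrix(stats::runif(36), 6, 6)
    g <- raster_grid(v, 100, 40, 0.5)
    br <- jenks_breaks(as.vector(v), 4)
    c1 <- classify_map(g, br)$grid$values
    bumped <- raster_grid(pmin(v + 0.2, 1), 100, 40, 0.5)
    c2 <- classify_map(bumped, br)$grid$values
    expect_true(all(c2 >= c1))
  })
})

test_that("class areas and land-use margins conserve the unmasked area", {
  withr::with_seed(31, {
    v <- matrix(stats::runif(400), 20, 20)
    v[sample(400, 60)] <- NA
    g <- raster_grid(v, 95, 42, 0.25)
    cm <- classify_map(g, jenks_breaks(v[!is.na(v)], 4))
    total <- sum(cell_area(g, as_tibble(g)$row[!is.na(as.vector(v))]))
    expect_equal(sum(cm$class_areas$area_km2), total, tolerance = 1e-9)

    lu <- raster_grid(matrix(sample(1:9, 400, replace = TRUE), 20, 20), 95, 42, 0.25)
    ct <- crosstab_landuse(cm, lu)
    expect_equal(sum(ct$area_km2), total, tolerance = 1e-9)
    # margins match the classified areas
    marg <- dplyr::summarise(dplyr::group_by(ct, suitability_class),
                             area = sum(area_km2))
    joined <- dplyr::left_join(cm$class_areas, marg,
                               by = c(class = "suitability_class"))
    expect_equal(joined$area_km2, joined$area, tolerance = 1e-9)
  })
})

test_that("crosstab handles constant and disjoint land use", {
  g <- raster_grid(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2), 100, 40, 0.5)
  cm <- classify_map(g, c(0.25, 0.5, 0.75))
  lu_const <- raster_grid(matrix(1, 2, 2), 100, 40, 0.5)
  ct <- crosstab_landuse(cm, lu_const)
  expect_equal(unique(ct$landuse), "grassland")
  expect_equal(sort(ct$area_km2), sort(cm$class_areas$area_km2[cm$class_areas$area_km2 > 0]))

  lu_gap <- raster_grid(matrix(NA_real_, 2, 2), 100, 40, 0.5)
  expect_warning(ct2 <- crosstab_landuse(cm, lu_gap), "disjoint")
  expect_equal(nrow(ct2), 0)

  lu_bad <- raster_grid(matrix(1, 3, 3), 100, 40, 0.5)
  expect_error(crosstab_landuse(cm, lu_bad), class = "ensdm_alignment_error")
})

test_that("the 2x2 hand cross-tabulation comes out exactly", {
  g <- raster_grid(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2), 100, 40, 0.5)
  cm <- classify_map(g, c(0.25, 0.5, 0.75))  # classes 0,3;3,0
  lu <- raster_grid(matrix(c(1, 2, 1, 2), 2, 2), 100, 40, 0.5)  # G,B;G,B rows
  ct <- crosstab_landuse(cm, lu)
  a0 <- cell_area(g, 0); a1 <- cell_area(g, 1)
  g_row <- ct[ct$landuse == "grassland", ]
  expect_setequal(round(g_row$area_km2, 9), round(c(a0, a0), 9))
  expect_setequal(g_row$suitability_class, c(0, 3))
  b_row <- ct[ct$landuse == "barren", ]
  expect_setequal(round(b_row$area_km2, 9), round(c(a1, a1), 9))
})

test_that("land-use correlation reproduces OLS identities", {
  x <- seq(10, 100, length.out = 20)
  samples <- tibble::tibble(tile = 1:20, landuse = "grassland",
                            landuse_area_km2 = x,
                            suitable_area_km2 = 3 * x + 7)
  res <- landuse_correlation(samples)
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 3)
  expect_equal(res$intercept, 7)

  withr::with_seed(3, {
    noisy <- tibble::tibble(tile = 1:100, landuse = "barren",
                            landuse_area_km2 = stats::runif(100),
                            suitable_area_km2 = sample(stats::runif(100)))
  })
  res2 <- landuse_correlation(noisy)
  expect_lt(res2$r_squared, 0.2)
  expect_equal(res2$r_squared, res2$pearson_r^2, tolerance = 1e-12)

  flat <- tibble::tibble(tile = 1:5, landuse = "water",
                         landuse_area_km2 = rep(2, 5),
                         suitable_area_km2 = stats::runif(5))
  res3 <- landuse_correlation(flat)
  expect_true(res3$degenerate)
  expect_true(is.na(res3$pearson_r))
})

test_that("distribution centres are area-weighted and stay in the box", {
  g1 <- raster_grid(matrix(c(NA, NA, 1, NA), 2, 2), 100, 40, 0.5)
  ctr <- distribution_center(g1)
  cc <- cell_center(g1, 0, 1)
  expect_equal(ctr$longitude, cc$longitude)
  expect_equal(ctr$latitude, cc$latitude)

  # two equal-latitude cells at lon 100.25 and 102.25: midpoint 101.25
  v <- matrix(0, 1, 5); v[1, c(1, 5)] <- 1
  g2 <- raster_grid(v, 100, 40, 0.5)
  expect_equal(distribution_center(g2)$longitude, 101.25)

  # two cells at different latitudes: pulled toward the larger (equatorward) cell
  v3 <- matrix(c(1, 0, 0, 0, 0, 1), 3, 2)  # cells at rows 0 and 2
  g3 <- raster_grid(v3, 100, 40, 1)
  ctr3 <- distribution_center(g3)
  unweighted_lat <- mean(c(cell_center(g3, 0, 0)$latitude, cell_center(g3, 2, 1)$latitude))
  expect_lt(ctr3$latitude, unweighted_lat)

  expect_error(distribution_center(raster_grid(matrix(0, 2, 2), 100, 40, 0.5)),
               class = "ensdm_empty_error")
})

test_that("centroid tracks use haversine steps on the fixed-radius sphere", {
  mk <- function(lon) {
    raster_grid(matrix(1, 1, 1), x_min = lon - 0.5, y_max = 0.5, cell_size = 1)
  }
  tr <- centroid_track(list(a = mk(0), b = mk(1), c = mk(1)))
  expect_equal(nrow(tr$steps), 2)
  expect_equal(tr$steps$distance_km[1], 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(tr$steps$distance_km[1], 111.19, tolerance = 1e-3)
  expect_equal(tr$steps$distance_km[2], 0)
  expect_equal(tr$steps$bearing_deg[1], 90)

  same <- centroid_track(list(p1 = mk(5), p2 = mk(5)))
  expect_equal(same$steps$distance_km, 0)

  expect_error(centroid_track(list(a = mk(0))), class = "ensdm_parameter_error")
  empty <- raster_grid(matrix(0, 1, 1), 0, 1, 1)
  expect_error(centroid_track(list(a = mk(0), bad = empty)), "bad",
               class = "ensdm_empty_error")
})

test_that("tile samples aggregate consistently with the global crosstab", {
  withr::with_seed(13, {
    v <- matrix(stats::runif(144), 12, 12)
    g <- raster_grid(v, 100, 40, 0.25)
    cm <- classify_map(g, jenks_breaks(as.vector(v), 4))
    lu <- raster_grid(matrix(sample(1:3, 144, replace = TRUE), 12, 12), 100, 40, 0.25)
  })
  smp <- tile_landuse_samples(cm, lu, tile_size = 4)
  expect_equal(length(unique(smp$tile)), 9)
  ct <- crosstab_landuse(cm, lu)
  for (lab in unique(ct$landuse)) {
    expect_equal(sum(smp$landuse_area_km2[smp$landuse == lab]),
                 sum(ct$area_km2[ct$landuse == lab]), tolerance = 1e-9)
  }
})
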