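#' Spatially thin occurrence records to one point per grid cell
#'
#' Occurrence records clustered inside one raster cell carry no extra
#' information at the modelling resolution and inflate spatial
#' autocorrelation, so at most one point is retained per cell: the first
#' encountered in input order. Points falling in NoData cells or outside
#' the grid are dropped, with the counts reported via a message and as
#' attributes (`n_dropped_masked`, `n_dropped_duplicate`) on the result.
#'
#' @param raw_points data frame with `longitude`/`latitude` (and optionally
#'   other columns, carried through).
#' @param grid a [raster_grid] or [align_stack] stack defining the working
#'   resolution and mask.
#' @return tibble of retained points, in input order.
#' @export
thin_occurrences <- function(raw_points, grid) {
  if (nrow(raw_points) < 1) {
    abort("`raw_points` must contain at least one point.", class = "ensdm_empty_error")
  }
  if (inherits(grid, "env_stack")) {
    mask <- grid$shared_mask
    ref <- grid$layers[[1]]
  } else {
    mask <- is.na(grid$values)
    ref <- grid
  }
  cl <- cell_of(ref, raw_points$longitude, raw_points$latitude)
  idx <- cl$row + 1 + cl$col * nrow(ref$values)
  bad <- is.na(idx)
  bad[!bad] <- mask[idx[!bad]]
  keep_first <- !bad & !duplicated(idx) & !is.na(idx)
  n_masked <- sum(bad)
  n_dup <- sum(!bad) - sum(keep_first)
  out <- as_tibble(raw_points)[keep_first, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("all points fall in NoData cells or outside the grid.",
          class = "ensdm_empty_error")
  }
  inform(sprintf(
    "thinning: kept %d of %d points (%d in NoData/outside cells, %d duplicate-cell)",
    nrow(out), nrow(raw_points), n_masked, n_dup))
  attr(out, "n_dropped_masked") <- n_masked
  attr(out, "n_dropped_duplicate") <- n_dup
  out
}

#' Generate pseudo-absence points
#'
#' Draws `n` cells uniformly without replacement from the unmasked cells of
#' the stack that are not occupied by a presence (optionally also excluding
#' cells within a Chebyshev distance of `min_distance_cells` cells of any
#' presence cell). The returned points are cell centres. With only
#' presences observed, these background points stand in for absences when
#' fitting the presence/absence learners.
#'
#' @param stack an [align_stack] result.
#' @param presences data frame with `longitude`/`latitude`.
#' @param n number of pseudo-absences (1000 by default, the standard design).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param min_distance_cells optional exclusion radius, in cells, around
#'   presence cells (default 0 = whole study-area mask).
#' @return tibble with `longitude`, `latitude`.
#' @export
sample_pseudo_absences <- function(stack, presences, n = 1000, seed = 1,
                                   min_distance_cells = 0) {
  ref <- stack$layers[[1]]
  d <- dim(ref$values)
  cl <- cell_of(ref, presences$longitude, presences$latitude)
  pres_idx <- unique(stats::na.omit(cl$row + 1 + cl$col * d[1]))
  free <- !as.vector(stack$shared_mask)
  free[pres_idx] <- FALSE
  if (min_distance_cells > 0 && length(pres_idx) > 0) {
    pr <- (pres_idx - 1) %% d[1]
    pc <- (pres_idx - 1) %/% d[1]
    all_r <- rep(seq_len(d[1]) - 1L, times = d[2])
    all_c <- rep(seq_len(d[2]) - 1L, each = d[1])
    cand <- which(free)
    for (k in seq_along(pr)) {
      near <- abs(all_r[cand] - pr[k]) <= min_distance_cells &
        abs(all_c[cand] - pc[k]) <= min_distance_cells
      free[cand[near]] <- FALSE
      cand <- cand[!near]
    }
  }
  avail <- which(free)
  if (length(avail) < n) {
    abort(sprintf(
      "cannot draw %d pseudo-absences: only %d unmasked presence-free cells available.",
      n, length(avail)), class = "ensdm_capacity_error")
  }
  chosen <- with_seed(seed, sample(avail, n, replace = FALSE))
  rows <- (chosen - 1) %% d[1]
  cols <- (chosen - 1) %/% d[1]
  cell_center(ref, rows, cols)
}

#' Assemble a labelled occurrence set
#'
#' Binds presences (label 1) and pseudo-absences (label 0) into the single
#' point table consumed by the evaluation and ensemble stages.
#'
#' @param presences,pseudo_absences data frames with `longitude`/`latitude`.
#' @param species optional species identifier stored in a `species` column.
#' @return tibble with `species`, `longitude`, `latitude`, `label`.
#' @export
build_occurrence_set <- function(presences, pseudo_absences, species = "species") {
  dplyr::bind_rows(
    tibble(species = species, longitude = presences$longitude,
           latitude = presences$latitude, label = 1L),
    tibble(species = species, longitude = pseudo_absences$longitude,
           latitude = pseudo_absences$latitude, label = 0L)
  )
}

#' Repeated stratified calibration/evaluation splits
#'
#' Adds `n_repeats` independent random splits to an occurrence set. Within
#' each repeat, `round(eval_fraction * n)` points of each label (rounded
#' half up, stratified by label) form the evaluation set and the rest the
#' calibration set — the standard 70/30 repeated-split design.
#'
#' @param occ occurrence tibble with a `label` column (see
#'   [build_occurrence_set]).
#' @param n_repeats number of repeats (default 4).
#' @param eval_fraction evaluation fraction per label (default 0.3).
#' @param seed integer seed.
#' @return `occ` with added character columns `split_1` ... `split_R`
#'   taking values `"calibration"` / `"evaluation"`.
#' @export
make_splits <- function(occ, n_repeats = 4, eval_fraction = 0.3, seed = 1) {
  labs <- occ$label
  n1 <- sum(labs == 1); n0 <- sum(labs == 0)
  if (n1 < 2 || n0 < 2) {
    abort(sprintf("need at least 2 points of each label to split (have %d presences, %d absences).",
                  n1, n0), class = "ensdm_split_error")
  }
  if (eval_fraction <= 0 || eval_fraction >= 1) {
    abort("`eval_fraction` must be in (0, 1).", class = "ensdm_split_error")
  }
  out <- as_tibble(occ)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      split <- rep("calibration", nrow(out))
      for (lb in c(0L, 1L)) {
        idx <- which(labs == lb)
        n_eval <- round_half_up(eval_fraction * length(idx))
        split[sample(idx, n_eval)] <- "evaluation"
      }
      out[[paste0("split_", r)]] <- split
    }
  })
  out
}

split_columns <- function(occ) grep("^split_\\d+$", names(occ), value = TRUE)

#' Read an occurrence CSV
#'
#' Expects columns `species`, `longitude`, `latitude` (WGS84 decimal
#' degrees); extra columns are carried through.
#' @param path CSV file.
#' @return tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("occurrence CSV %s is missing column(s): %s",
                  path, paste(miss, collapse = ", ")),
          class = "ensdm_format_error")
  }
  as_tibble(df)
}
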