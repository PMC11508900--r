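#' Assemble a pipeline run configuration
#'
#' Collects every input and tunable of a full analysis run. Stacks,
#' occurrences and land use may be given either as in-memory objects
#' (`env_stack`, tibble, `raster_grid`) or as paths (a directory of
#' `.asc` layers; a CSV; an `.asc` file). The `"current"` period is
#' mandatory — it anchors calibration; any other periods are projected
#' onto without recalibration.
#'
#' @param periods named list of stacks (or stack directories), one per
#'   climate period; must include `"current"`.
#' @param occurrences presence table (`species`, `longitude`, `latitude`)
#'   or CSV path.
#' @param landuse optional land-use raster (codes per
#'   [landuse_legend]) or `.asc` path.
#' @param species species identifier for outputs.
#' @param thinning thin presences to one per cell first?
#' @param n_pseudo_absences background points to draw (default 1000).
#' @param n_repeats calibration/evaluation repeats (default 4).
#' @param eval_fraction evaluation fraction per label (default 0.3).
#' @param screening_threshold pairwise `|r|` cutoff (default 0.8).
#' @param models committee member names (default all of [sdm_models()]).
#' @param weight_metric,inclusion_cutoff see [build_ensemble].
#' @param k_classes habitat classes for natural breaks (default 4).
#' @param tile_size tile edge (cells) for the land-use correlation
#'   (default 10).
#' @param breaks_from `"per_period"` (each period map classified at its
#'   own natural breaks) or `"current"` (current-period breaks applied to
#'   all periods).
#' @param seed root seed; all stage seeds are derived from it.
#' @return list of class `sdm_run_config`.
#' @export
sdm_run_config <- function(periods, occurrences, landuse = NULL,
                           species = "species", thinning = TRUE,
                           n_pseudo_absences = 1000, n_repeats = 4,
                           eval_fraction = 0.3, screening_threshold = 0.8,
                           models = sdm_models(),
                           weight_metric = "TSS", inclusion_cutoff = 0,
                           k_classes = 4, tile_size = 10,
                           breaks_from = "per_period", seed = 1) {
  structure(
    list(periods = periods, occurrences = occurrences, landuse = landuse,
         species = species, thinning = thinning,
         n_pseudo_absences = n_pseudo_absences, n_repeats = n_repeats,
         eval_fraction = eval_fraction,
         screening_threshold = screening_threshold, models = models,
         weight_metric = weight_metric, inclusion_cutoff = inclusion_cutoff,
         k_classes = k_classes, tile_size = tile_size,
         breaks_from = breaks_from, seed = as.integer(seed)),
    class = "sdm_run_config"
  )
}

#' Validate a run configuration
#'
#' Checks every path, range and enumeration and reports all violations
#' (not only the first).
#'
#' @param config an [sdm_run_config].
#' @return tibble with columns `field`, `problem`; zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1]] <<- tibble(field = field, problem = problem)

  per <- config$periods
  if (is.null(per) || length(per) == 0 || is.null(names(per)) || any(!nzchar(names(per)))) {
    bad("periods", "must be a non-empty named list")
  } else {
    if (anyDuplicated(names(per))) bad("periods", "period names must be unique")
    if (!("current" %in% names(per))) bad("periods", "a 'current' period is required")
    for (nm in names(per)) {
      p <- per[[nm]]
      if (is.character(p)) {
        if (!dir.exists(p)) bad(paste0("periods$", nm), sprintf("directory not found: %s", p))
      } else if (!inherits(p, "env_stack")) {
        bad(paste0("periods$", nm), "must be an env_stack or a directory path")
      }
    }
  }
  occ <- config$occurrences
  if (is.character(occ)) {
    if (!file.exists(occ)) bad("occurrences", sprintf("file not found: %s", occ))
  } else if (!is.data.frame(occ)) {
    bad("occurrences", "must be a data frame or CSV path")
  } else if (!all(c("longitude", "latitude") %in% names(occ))) {
    bad("occurrences", "needs longitude and latitude columns")
  }
  if (!is.null(config$landuse) && is.character(config$landuse) &&
      !file.exists(config$landuse)) {
    bad("landuse", sprintf("file not found: %s", config$landuse))
  }
  if (!is.numeric(config$eval_fraction) || config$eval_fraction <= 0 ||
      config$eval_fraction >= 1) {
    bad("eval_fraction", "must be in (0, 1)")
  }
  if (!is_count(config$n_repeats) || config$n_repeats < 1) bad("n_repeats", "must be a positive count")
  if (!is_count(config$n_pseudo_absences) || config$n_pseudo_absences < 1) {
    bad("n_pseudo_absences", "must be a positive count")
  }
  unknown <- setdiff(config$models, sdm_models())
  if (length(unknown) > 0) {
    bad("models", sprintf("unknown model name(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(config$models) == 0) bad("models", "at least one model is required")
  if (!(config$weight_metric %in% c("TSS", "AUC", "KAPPA"))) {
    bad("weight_metric", "must be TSS, AUC or KAPPA")
  }
  if (!is.numeric(config$screening_threshold) || config$screening_threshold <= 0 ||
      config$screening_threshold > 1) {
    bad("screening_threshold", "must be in (0, 1]")
  }
  if (!is_count(config$k_classes) || config$k_classes < 2) bad("k_classes", "must be >= 2")
  if (!is_count(config$tile_size) || config$tile_size < 1) bad("tile_size", "must be >= 1")
  if (!(config$breaks_from %in% c("per_period", "current"))) {
    bad("breaks_from", "must be 'per_period' or 'current'")
  }
  if (length(v) == 0) tibble(field = character(), problem = character())
  else dplyr::bind_rows(v)
}

#' Read all `.asc` layers of a directory as a stack
#'
#' Layer names are the file names without extension.
#' @param path directory of ESRI ASCII grids.
#' @return an [align_stack] stack.
#' @export
read_stack_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("no .asc layers found in %s", path), class = "ensdm_format_error")
  }
  layers <- lapply(files, read_raster)
  align_stack(layers, sub("\\.asc$", "", basename(files)))
}

#' Write a stack as a directory of `.asc` layers
#' @param stack an `env_stack`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_stack_dir <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in stack$layer_names) {
    write_raster(stack$layers[[nm]], file.path(path, paste0(nm, ".asc")))
  }
  invisible(path)
}

resolve_stack <- function(x) if (is.character(x)) read_stack_dir(x) else x
resolve_landuse <- function(x) if (is.character(x)) read_raster(x) else x

#' Run the full ensemble-SDM pipeline
#'
#' Executes the complete stage sequence — thinning, pseudo-absence
#' sampling, repeated splits, correlation/contribution screening,
#' committee evaluation, weighted-ensemble construction, per-period
#' projection, natural-breaks classification with areas, optional
#' land-use overlay and correlation, and centroid-shift tracking — and
#' writes every product plus a machine-readable manifest into `out_dir`.
#' Reruns with an identical configuration are bit-identical.
#'
#' @param config an [sdm_run_config]; validated first.
#' @param out_dir run directory (created; existing files overwritten).
#' @return invisibly, a list with the in-memory results (`occ`,
#'   `screening`, `records`, `ensemble`, `threshold`, `projections`,
#'   `classified`, `areas`, `track`, `landuse_cor`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    abort(paste0("invalid configuration:\n",
                 paste(sprintf("  - %s: %s", problems$field, problems$problem),
                       collapse = "\n")),
          class = "ensdm_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  seed <- config$seed
  stage <- "load"
  result <- list()
  on.exit({
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }, add = TRUE)
  tryCatch({
    stacks <- lapply(config$periods, resolve_stack)
    current <- stacks[["current"]]
    logf(stage, "loaded %d period stack(s): %s; %d layers each",
         length(stacks), paste(names(stacks), collapse = ", "),
         length(current$layer_names))

    stage <- "occurrences"
    occ_raw <- if (is.character(config$occurrences)) {
      read_occurrences(config$occurrences)
    } else as_tibble(config$occurrences)
    logf(stage, "%d raw presence record(s)", nrow(occ_raw))
    pres <- if (config$thinning) {
      suppressMessages(thin_occurrences(occ_raw, current))
    } else occ_raw
    logf(stage, "%d presence(s) after thinning (%d dropped NoData/outside, %d duplicate-cell)",
         nrow(pres), attr(pres, "n_dropped_masked") %||% 0,
         attr(pres, "n_dropped_duplicate") %||% 0)
    pa <- sample_pseudo_absences(current, pres, n = config$n_pseudo_absences,
                                 seed = derive_seed(seed, "pseudo_absences"))
    occ <- build_occurrence_set(pres, pa, species = config$species)
    occ <- make_splits(occ, n_repeats = config$n_repeats,
                       eval_fraction = config$eval_fraction,
                       seed = derive_seed(seed, "splits"))
    logf(stage, "%d presences + %d pseudo-absences; %d repeat split(s)",
         sum(occ$label == 1), sum(occ$label == 0), config$n_repeats)

    stage <- "extract"
    ext <- extract_values(current, occ)
    if (any(ext$status != "ok")) {
      abort(sprintf("%d occurrence point(s) fall outside the usable grid",
                    sum(ext$status != "ok")), class = "ensdm_data_error")
    }
    covars <- ext[, current$layer_names, drop = FALSE]

    stage <- "screening"
    corr_in <- covars
    use <- "everything"
    if ("aspect" %in% names(corr_in)) {
      # flat-aspect sentinel cells are excluded from the correlation
      corr_in$aspect[corr_in$aspect == -1] <- NA_real_
      use <- "pairwise.complete.obs"
    }
    corr <- pearson_matrix(corr_in, use = use)
    prelim <- list()
    for (nm in config$models) {
      f <- tryCatch(fit_sdm(sdm_spec(nm, seed = derive_seed(seed, paste0("prelim_", nm))),
                            covars, occ$label),
                    error = function(e) NULL)
      if (!is.null(f)) prelim[[nm]] <- f
    }
    if (length(prelim) == 0) {
      abort("every preliminary model fit failed.", class = "ensdm_fit_error")
    }
    prelim_ens <- structure(
      list(members = prelim, weights = stats::setNames(rep(1, length(prelim)), names(prelim)),
           weight_metric = "equal", inclusion_cutoff = 0),
      class = "sdm_ensemble")
    contrib <- permutation_importance(prelim_ens, covars,
                                      seed = derive_seed(seed, "screening_importance"))
    screening <- screen_variables(corr, stats::setNames(contrib$importance, contrib$variable),
                                  threshold = config$screening_threshold)
    write_screening_report(screening, file.path(out_dir, "screening_correlation.csv"),
                           file.path(out_dir, "screening_decisions.json"))
    logf(stage, "kept %d of %d variable(s): %s", length(screening$kept),
         length(current$layer_names), paste(screening$kept, collapse = ", "))
    kept <- screening$kept
    covars_kept <- covars[, kept, drop = FALSE]

    stage <- "evaluate"
    records <- evaluate_models(config$models, occ, covars_kept,
                               seed = derive_seed(seed, "evaluation_fits"))
    utils::write.csv(as.data.frame(records), file.path(out_dir, "evaluation_records.csv"),
                     row.names = FALSE)
    logf(stage, "%d evaluation record(s) (%d failed)", nrow(records), sum(records$failed))

    stage <- "ensemble"
    full_fits <- list()
    for (nm in config$models) {
      f <- tryCatch(fit_sdm(sdm_spec(nm, seed = derive_seed(seed, paste0("full_", nm))),
                            covars_kept, occ$label),
                    error = function(e) NULL)
      if (!is.null(f)) full_fits[[nm]] <- f
    }
    ens <- build_ensemble(records, full_fits, weight_metric = config$weight_metric,
                          inclusion_cutoff = config$inclusion_cutoff)
    thr <- ensemble_threshold(ens, records)
    logf(stage, "%d member(s); pooled max-TSS threshold %.4f (TSS %.3f)",
         length(ens$members), thr$threshold, thr$tss)

    stage <- "project"
    proj_dir <- file.path(out_dir, "projections")
    cls_dir <- file.path(out_dir, "classified")
    bin_dir <- file.path(out_dir, "binary")
    for (d in c(proj_dir, cls_dir, bin_dir)) dir.create(d, showWarnings = FALSE)
    projections <- list(); classified <- list(); binaries <- list()
    breaks_current <- NULL
    if (config$breaks_from == "current") {
      projections[["current"]] <- project_map(ens, stacks[["current"]])
      vals_cur <- projections[["current"]]$values
      breaks_current <- jenks_breaks(vals_cur[!is.na(vals_cur)], k = config$k_classes)
    }
    area_rows <- list()
    for (p in names(stacks)) {
      sm <- projections[[p]] %||% project_map(ens, stacks[[p]])
      projections[[p]] <- sm
      write_raster(sm, file.path(proj_dir, paste0(p, ".asc")))
      vals <- sm$values[!is.na(sm$values)]
      br <- if (config$breaks_from == "current") breaks_current
            else jenks_breaks(vals, k = config$k_classes)
      cm <- classify_map(sm, br)
      classified[[p]] <- cm
      write_raster(cm$grid, file.path(cls_dir, paste0(p, ".asc")))
      binaries[[p]] <- binarize_map(sm, thr$threshold)
      write_raster(binaries[[p]], file.path(bin_dir, paste0(p, ".asc")))
      area_rows[[p]] <- dplyr::mutate(cm$class_areas, period = p, .before = 1)
      logf(stage, "period %s: projected, classified (breaks %s)", p,
           paste(signif(br, 5), collapse = ", "))
    }
    areas <- dplyr::bind_rows(area_rows)
    utils::write.csv(as.data.frame(areas), file.path(out_dir, "habitat_areas.csv"),
                     row.names = FALSE)

    stage <- "centroids"
    track <- NULL
    if (length(binaries) >= 2) {
      track <- centroid_track(binaries, names(binaries))
      utils::write.csv(as.data.frame(track$centers), file.path(out_dir, "centroids.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(track$steps), file.path(out_dir, "centroid_steps.csv"),
                       row.names = FALSE)
      logf(stage, "%d period centre(s); max step %.2f km", nrow(track$centers),
           max(track$steps$distance_km))
    } else {
      logf(stage, "single period; centroid tracking skipped")
    }

    stage <- "landuse"
    landuse_cor <- NULL; cross <- NULL
    if (!is.null(config$landuse)) {
      lu <- resolve_landuse(config$landuse)
      cross <- crosstab_landuse(classified[["current"]], lu)
      utils::write.csv(as.data.frame(cross), file.path(out_dir, "landuse_crosstab.csv"),
                       row.names = FALSE)
      samples <- tile_landuse_samples(classified[["current"]], lu,
                                      tile_size = config$tile_size)
      landuse_cor <- landuse_correlation(samples)
      utils::write.csv(as.data.frame(landuse_cor),
                       file.path(out_dir, "landuse_correlation.csv"), row.names = FALSE)
      logf(stage, "cross-tabulated %d land-use class(es) over %d tile sample(s)",
           length(unique(cross$landuse)), length(unique(samples$tile)))
    } else {
      logf(stage, "no land-use layer configured; overlay skipped")
    }

    stage <- "manifest"
    utils::write.csv(as.data.frame(occ), file.path(out_dir, "occurrence_set.csv"),
                     row.names = FALSE)
    manifest <- list(
      species = config$species,
      parameters = list(
        thinning = config$thinning,
        n_pseudo_absences = config$n_pseudo_absences,
        n_repeats = config$n_repeats, eval_fraction = config$eval_fraction,
        screening_threshold = config$screening_threshold,
        models = config$models, weight_metric = config$weight_metric,
        inclusion_cutoff = config$inclusion_cutoff,
        k_classes = config$k_classes, tile_size = config$tile_size,
        breaks_from = config$breaks_from),
      seeds = list(
        root = seed,
        pseudo_absences = derive_seed(seed, "pseudo_absences"),
        splits = derive_seed(seed, "splits"),
        screening_importance = derive_seed(seed, "screening_importance"),
        evaluation_fits = derive_seed(seed, "evaluation_fits")),
      periods = names(stacks),
      variables = list(candidates = current$layer_names,
                       kept = screening$kept,
                       dropped = screening$dropped$variable),
      weights = as.list(ens$weights),
      binarization = list(rule = "max_TSS_pooled_evaluation",
                          threshold = thr$threshold, tss = thr$tss),
      break_points = lapply(classified, function(cm) cm$break_points),
      n_evaluation_records = nrow(records),
      n_failed_records = sum(records$failed)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf(stage, "manifest written")

    result <- list(occ = occ, screening = screening, records = records,
                   ensemble = ens, threshold = thr, projections = projections,
                   classified = classified, binaries = binaries, areas = areas,
                   track = track, landuse_cross = cross,
                   landuse_cor = landuse_cor, manifest = manifest)
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "ensdm_pipeline_error", parent = e)
  })
  invisible(result)
}
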