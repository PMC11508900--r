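#' Build a weighted committee from evaluation records
#'
#' Each member model's weight is its mean evaluation metric across repeats
#' (TSS by default), floored at 0, and zeroed when below
#' `inclusion_cutoff`; models whose fits failed get weight 0. Better
#' performing members therefore drive the combined prediction harder. The
#' committee prediction is the weighted average `sum(W_i P_i) / sum(W_i)`.
#'
#' @param records [evaluate_models] output.
#' @param models named list of full-data [fit_sdm] refits, one per model
#'   name appearing in `records`.
#' @param weight_metric metric used as weight: `"TSS"`, `"AUC"` or
#'   `"KAPPA"` (default TSS).
#' @param inclusion_cutoff minimum mean metric for a member to keep a
#'   nonzero weight (default 0).
#' @return object of class `sdm_ensemble`.
#' @export
build_ensemble <- function(records, models, weight_metric = c("TSS", "AUC", "KAPPA"),
                           inclusion_cutoff = 0) {
  weight_metric <- match.arg(weight_metric)
  col <- c(TSS = "tss", AUC = "auc", KAPPA = "kappa")[[weight_metric]]
  means <- records |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(metric = if (all(.data$failed)) NA_real_ else
      mean(.data[[col]][!.data$failed]), .groups = "drop")
  w <- stats::setNames(pmax(0, means$metric), means$model)
  w[is.na(w)] <- 0
  w[w < inclusion_cutoff] <- 0
  w <- w[intersect(names(models), names(w))]  # keep the committee order
  if (length(w) == 0 || sum(w) <= 0) {
    abort("no model meets the inclusion cutoff; the ensemble would be empty.",
          class = "ensdm_empty_ensemble_error")
  }
  keep <- names(w)[w > 0]
  structure(
    list(members = models[keep], weights = w[keep],
         weight_metric = weight_metric, inclusion_cutoff = inclusion_cutoff,
         member_metrics = stats::setNames(means$metric, means$model)),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %d member(s), weights by mean %s (cutoff %.3g)\n",
              length(x$members), x$weight_metric, x$inclusion_cutoff))
  wn <- x$weights / sum(x$weights)
  for (nm in names(x$weights)) {
    cat(sprintf("  %-12s W = %.4f (normalised %.3f)\n", nm, x$weights[[nm]], wn[[nm]]))
  }
  invisible(x)
}

#' Predict suitability from a weighted committee
#'
#' Returns `sum(W_i P_i) / sum(W_i)` over members with non-missing
#' predictions for each row; rows where every member is missing give `NA`.
#' A convex combination: always within the range of the member
#' predictions.
#'
#' @param object an [build_ensemble] result.
#' @param newdata covariate data frame.
#' @param ... unused.
#' @return numeric suitability in `[0, 1]` per row.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  P <- vapply(object$members, function(m) predict(m, newdata),
              numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  W <- matrix(rep(object$weights, each = nrow(P)), nrow = nrow(P))
  W[is.na(P)] <- 0
  P[is.na(P)] <- 0
  tot <- rowSums(W)
  out <- rowSums(W * P) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Project a committee onto a raster stack
#'
#' Applies [predict.sdm_ensemble] to every cell clear in the stack's
#' shared mask; masked cells stay NoData. The stack may be any climate
#' period as long as it carries the member variables under the same layer
#' names (no recalibration is performed).
#'
#' @param ens an `sdm_ensemble` (or single `sdm_fit`).
#' @param stack an [align_stack] result.
#' @return [raster_grid] of suitability in `[0, 1]`.
#' @export
project_map <- function(ens, stack) {
  vars <- if (inherits(ens, "sdm_ensemble")) ens$members[[1]]$variables else ens$variables
  miss <- setdiff(vars, stack$layer_names)
  if (length(miss) > 0) {
    abort(sprintf("projection stack is missing layer(s): %s",
                  paste(miss, collapse = ", ")),
          class = "ensdm_schema_error")
  }
  cells <- stack_cell_table(stack)
  s <- predict(ens, cells[, vars, drop = FALSE])
  ref <- stack$layers[[1]]
  m <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  m[cbind(cells$row + 1, cells$col + 1)] <- s
  raster_grid(m, ref$x_min, ref$y_max, ref$cell_size)
}

#' Pooled max-TSS threshold for ensemble binarisation
#'
#' Combines the per-repeat evaluation scores retained by
#' [evaluate_models] into pooled ensemble scores (weighted by the
#' ensemble's member weights, per repeat and point) and returns the
#' max-TSS threshold of the pooled set. This is the threshold used to
#' binarise suitability maps before centroid tracking.
#'
#' @param ens an `sdm_ensemble`.
#' @param records the [evaluate_models] output used to build it.
#' @return list with `threshold` and `tss`.
#' @export
ensemble_threshold <- function(ens, records) {
  preds <- attr(records, "predictions")
  if (is.null(preds) || nrow(preds) == 0) {
    abort("records carry no evaluation predictions.", class = "ensdm_data_error")
  }
  w <- ens$weights
  pooled <- preds |>
    dplyr::filter(.data$model %in% names(w)) |>
    dplyr::mutate(w = unname(w[.data$model])) |>
    dplyr::group_by(.data$repeat_index, .data$point) |>
    dplyr::summarise(score = sum(.data$w * .data$score) / sum(.data$w),
                     label = .data$label[1], .groups = "drop")
  best_threshold_by_tss(pooled$score, pooled$label)
}

#' Binarise a suitability map at a threshold
#'
#' Cells with suitability `>= threshold` become 1, others 0; NoData stays
#' NoData.
#' @param suitability a [raster_grid].
#' @param threshold binarisation threshold in `[0, 1]`.
#' @return [raster_grid] of 0/1.
#' @export
binarize_map <- function(suitability, threshold) {
  m <- suitability$values
  m[!is.na(m)] <- as.numeric(m[!is.na(m)] >= threshold)
  raster_grid(m, suitability$x_min, suitability$y_max, suitability$cell_size)
}
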