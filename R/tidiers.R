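#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an ensemble: one row per member
#'
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @return tibble: `model`, `weight`, `weight_normalized`, `metric_mean`.
#' @exportS3Method generics::tidy
tidy.sdm_ensemble <- function(x, ...) {
  tibble(model = names(x$weights),
         weight = unname(x$weights),
         weight_normalized = unname(x$weights / sum(x$weights)),
         metric_mean = unname(x$member_metrics[names(x$weights)]))
}

#' One-row ensemble summary
#'
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @return tibble: `n_members`, `weight_metric`, `inclusion_cutoff`,
#'   `max_weight_model`.
#' @exportS3Method generics::glance
glance.sdm_ensemble <- function(x, ...) {
  tibble(n_members = length(x$members),
         weight_metric = x$weight_metric,
         inclusion_cutoff = x$inclusion_cutoff,
         max_weight_model = names(x$weights)[which.max(x$weights)])
}

#' Tidy a screening report: one row per candidate variable
#'
#' @param x a `screening_report`.
#' @param ... unused.
#' @return tibble: `variable`, `contribution`, `kept`, `reason`.
#' @exportS3Method generics::tidy
tidy.screening_report <- function(x, ...) {
  vars <- colnames(x$correlation)
  reason <- stats::setNames(rep(NA_character_, length(vars)), vars)
  reason[x$dropped$variable] <- x$dropped$reason
  tibble(variable = vars,
         contribution = unname(x$contribution[vars]),
         kept = vars %in% x$kept,
         reason = unname(reason))
}

#' Tidy a classified habitat map: one row per class
#'
#' @param x a `classified_map`.
#' @param ... unused.
#' @return tibble: `class`, `label`, `area_km2`.
#' @exportS3Method generics::tidy
tidy.classified_map <- function(x, ...) {
  labels <- c("no suitability", "low", "medium", "high")
  n <- nrow(x$class_areas)
  dplyr::mutate(x$class_areas,
                label = if (n == 4) labels else paste0("class_", .data$class),
                .after = "class")
}

#' Tidy a centroid track: one row per step
#'
#' @param x a `centroid_track`.
#' @param ... unused.
#' @return the `steps` tibble.
#' @exportS3Method generics::tidy
tidy.centroid_track <- function(x, ...) x$steps

#' One-row summary of an evaluation table
#'
#' @param x an `sdm_evaluation` tibble.
#' @param ... unused.
#' @return tibble: record counts and cross-model metric means.
#' @exportS3Method generics::glance
glance.sdm_evaluation <- function(x, ...) {
  ok <- !x$failed
  tibble(n_records = nrow(x), n_failed = sum(x$failed),
         mean_auc = mean(x$auc[ok]), mean_kappa = mean(x$kappa[ok]),
         mean_tss = mean(x$tss[ok]))
}
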