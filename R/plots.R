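#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_hline
#'   geom_point geom_path scale_fill_viridis_c facet_wrap labs theme_minimal
NULL

#' Plot a raster grid
#'
#' @param object a [raster_grid].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df[!is.na(df$value), ], aes(.data$longitude, .data$latitude,
                                     fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "Longitude", y = "Latitude", fill = "value") +
    theme_minimal()
}

#' Plot response curves with their favourability cutoff
#'
#' @param object a [response_curve] result.
#' @param ... unused.
#' @return a ggplot faceted by variable.
#' @exportS3Method ggplot2::autoplot
autoplot.response_curves <- function(object, ...) {
  ggplot(object$curves, aes(.data$value, .data$suitability)) +
    geom_line() +
    geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    facet_wrap(~variable, scales = "free_x") +
    labs(x = "Covariate value", y = "Ensemble suitability") +
    theme_minimal()
}

#' Plot a centroid track across periods
#'
#' @param object a [centroid_track] result.
#' @param ... unused.
#' @return a ggplot of the centre path.
#' @exportS3Method ggplot2::autoplot
autoplot.centroid_track <- function(object, ...) {
  ggplot(object$centers, aes(.data$longitude, .data$latitude)) +
    geom_path(linetype = "dotted") +
    geom_point(aes(colour = .data$period), size = 3) +
    labs(x = "Longitude", y = "Latitude", colour = "Period") +
    theme_minimal()
}

#' Plot per-model evaluation metrics
#'
#' Boxplots of AUC, kappa and TSS across repeats for each committee
#' member.
#' @param records an [evaluate_models] result.
#' @return a ggplot.
#' @export
plot_evaluation <- function(records) {
  df <- records |>
    dplyr::filter(!.data$failed) |>
    tidyr::pivot_longer(c("auc", "kappa", "tss"), names_to = "metric",
                        values_to = "value")
  ggplot(df, aes(.data$model, .data$value)) +
    ggplot2::geom_boxplot() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
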