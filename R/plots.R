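#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a quarter-averaged importance heatmap
#'
#' Features x quarters tile plot of mean importance scores, features
#' ordered by overall mean importance.
#'
#' @param object An [importance_heatmap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_heatmap <- function(object, ...) {
  ord <- rownames(importance_matrix(object))
  df <- dplyr::mutate(tibble::as_tibble(object),
                      feature = factor(.data$feature, levels = rev(ord)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quarter, y = .data$feature,
                                   fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "importance") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Stage %d importance, averaged by quarter",
                                  attr(object, "stage"))) +
    ggplot2::theme_minimal()
}

#' Plot a prediction map
#'
#' Baseline, correction and final layers side by side on the map grid;
#' pixels outside the wetlands are blank.
#'
#' @param object A [predict_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_map <- function(object, ...) {
  df <- dplyr::bind_rows(tidy(object$baseline), tidy(object$correction),
                         tidy(object$final))
  df$band <- factor(df$band, levels = c("baseline", "correction", "final"))
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~band) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "mg/L") +
    ggplot2::labs(x = NULL, y = NULL, title = object$key) +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted scatter for a fitted model
#'
#' @param model A `two_stage_model`.
#' @param test Held-out feature rows.
#' @return A ggplot object with the 1:1 line.
#' @export
plot_validation <- function(model, test) {
  pr <- suppressWarnings(predict(model, test))
  df <- tibble::tibble(observed = test$concentration, predicted = pr$final)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "observed (mg/L)", y = "predicted (mg/L)") +
    ggplot2::theme_minimal()
}
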