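# ggplot2 views of the package's result types.

#' Plot spectra colored by SSC
#'
#' @param object A `spectral_dataset`.
#' @param ... Unused.
#' @return A ggplot: one reflectance curve per sample, colored by SSC.
#' @export
autoplot.spectral_dataset <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -c("sample_id", "ssc"),
    names_to = "wavelength", values_to = "reflectance",
    names_transform = as.numeric
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
                                     group = .data$sample_id,
                                     color = .data$ssc)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance",
                  color = "SSC (% Brix)") +
    ggplot2::theme_minimal()
}

#' Plot grid results per pre-processing group
#'
#' @param object A `result_table`.
#' @param metric Which metric column to show (default `"rmse_p"`).
#' @param ... Unused.
#' @return A ggplot dot chart of the metric by selector, faceted by
#'   pre-processor.
#' @export
autoplot.result_table <- function(object, metric = "rmse_p", ...) {
  df <- tibble::as_tibble(object)
  df$select <- factor(df$select, levels = selector_methods())
  ggplot2::ggplot(df[!df$failed, ],
                  ggplot2::aes(.data$select, .data[[metric]])) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~preprocess) +
    ggplot2::labs(x = "Selection method", y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a best-frequency tally
#'
#' @param object A `frequency_tally`.
#' @param ... Unused.
#' @export
autoplot.frequency_tally <- function(object, ...) {
  long <- tidy(object)
  long$select <- factor(long$select, levels = selector_methods())
  ggplot2::ggplot(long, ggplot2::aes(.data$select, .data$preprocess,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::labs(x = "Selection method", y = "Pre-processing",
                  fill = "Best count") +
    ggplot2::theme_minimal()
}

#' Measured-versus-predicted scatter data and plot
#'
#' `prediction_scatter()` returns a tidy tibble of measured and predicted
#' SSC for the calibration and prediction sets of a fitted stack (or any
#' predictor closure); `plot_predictions()` draws it.
#'
#' @param model A `stack_model`.
#' @param data The `spectral_dataset` the split refers to.
#' @param split The [spxy_split()] used to fit the model.
#' @return A tibble with `sample_id`, `set`, `measured`, `predicted`.
#' @export
prediction_scatter <- function(model, data, split) {
  X <- spectra_matrix(data)
  y <- spectra_ssc(data)
  pred <- stack_predict(model, X)
  set <- rep("calibration", nrow(X))
  set[split$pred_idx] <- "prediction"
  tibble::tibble(sample_id = data$sample_id, set = set,
                 measured = y, predicted = pred)
}

#' @rdname prediction_scatter
#' @export
plot_predictions <- function(model, data, split) {
  df <- prediction_scatter(model, data, split)
  ggplot2::ggplot(df, ggplot2::aes(.data$measured, .data$predicted,
                                   color = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Measured SSC (% Brix)", y = "Predicted SSC (% Brix)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
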