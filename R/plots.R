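# ggplot2 visualisations of selections, reports and loss curves.

#' Plot wavelength-selection diagnostics
#'
#' For SPA: validation RMSE against subset size, with the chosen size
#' marked. For CARS: RMSECV and retained-variable count against the
#' Monte-Carlo iteration, with the chosen iteration marked.
#'
#' @param object a `vs_selection`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.vs_selection <- function(object, ...) {
  if (object$method == "SPA") {
    df <- tibble(size = seq_along(object$rmse_path), rmse = object$rmse_path)
    ggplot(df, aes(.data$size, .data$rmse)) +
      geom_line() + geom_point(size = 0.8) +
      geom_vline(xintercept = object$best_size, linetype = "dashed") +
      labs(x = "Number of selected wavelengths", y = "Validation RMSE",
           title = "SPA wavelength selection") +
      theme_minimal()
  } else {
    df <- bind_rows(
      tibble(iteration = seq_along(object$rmsecv_path),
             value = object$rmsecv_path, what = "RMSECV"),
      tibble(iteration = seq_along(object$retained_path),
             value = as.numeric(object$retained_path),
             what = "Sampled variables"))
    ggplot(df, aes(.data$iteration, .data$value)) +
      geom_line() +
      geom_vline(xintercept = object$chosen_iteration, linetype = "dashed") +
      facet_wrap(~what, scales = "free_y", ncol = 1) +
      labs(x = "Monte-Carlo iteration", y = NULL,
           title = "CARS wavelength selection") +
      theme_minimal()
  }
}

#' Plot a pipeline report
#'
#' Test-set correlation coefficient per grid cell, grouped by model and
#' coloured by feature mode.
#'
#' @param object a `vs_report` from [run_pipeline()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.vs_report <- function(object, ...) {
  ggplot(object, aes(.data$preprocessing, .data$R_P, fill = .data$mode)) +
    geom_col(position = "dodge") +
    facet_wrap(~model) +
    labs(x = NULL, y = "Test-set correlation coefficient (R)",
         fill = "Features") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Plot a CNN training loss curve
#'
#' @param model a fitted `vs_cnn`.
#' @return A ggplot of training MSE per epoch.
#' @export
plot_loss_curve <- function(model) {
  stopifnot(inherits(model, "vs_cnn"))
  ggplot(tidy(model), aes(.data$epoch, .data$mse)) +
    geom_line() +
    labs(x = "Epoch", y = "Training MSE", title = "1D-CNN training loss") +
    theme_minimal()
}

#' Plot predicted against observed vitality
#'
#' @param model a fitted `vs_model`.
#' @param X predictor matrix.
#' @param y observed vitality (cm).
#' @return A ggplot with the identity line.
#' @export
plot_predictions <- function(model, X, y) {
  df <- tibble(observed = y, predicted = predict(model, X))
  ggplot(df, aes(.data$observed, .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_point(alpha = 0.7) +
    labs(x = "Observed vitality (cm)", y = "Predicted vitality (cm)") +
    theme_minimal()
}
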