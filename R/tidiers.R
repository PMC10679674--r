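# broom-style tidy()/glance() methods for fitted objects and results.

#' @describeIn fit_plsr Tidy the coefficient vector: one row per predictor
#'   with its regression coefficient.
#' @param x,object a fitted `vs_plsr`.
#' @param ... unused.
#' @export
tidy.vs_plsr <- function(x, ...) {
  tibble(term = seq_along(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @describeIn fit_plsr One-row model summary.
#' @export
glance.vs_plsr <- function(x, ...) {
  tibble(components = x$components, VN = x$VN)
}

#' @describeIn fit_svr One-row model summary.
#' @param x a fitted `vs_svr`.
#' @param ... unused.
#' @export
glance.vs_svr <- function(x, ...) {
  tibble(kernel = "rbf", cost = x$cost, epsilon = x$epsilon,
         gamma = x$gamma,
         n_support = if (is.null(x$fit)) 0L else x$fit$tot.nSV,
         VN = x$VN)
}

#' @describeIn fit_cnn Tidy the training loss curve: one row per epoch.
#' @param x a fitted `vs_cnn`.
#' @param ... unused.
#' @export
tidy.vs_cnn <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_curve), mse = x$loss_curve)
}

#' @describeIn fit_cnn One-row model summary.
#' @export
glance.vs_cnn <- function(x, ...) {
  s <- x$spec
  tibble(conv1_filters = s$conv1_filters, conv2_filters = s$conv2_filters,
         fc_units = s$fc_units, epochs = s$epochs, lr = s$lr,
         batch = s$batch, final_mse = x$loss_curve[length(x$loss_curve)],
         VN = x$VN)
}

#' Tidy a wavelength selection
#'
#' One row per selected wavelength index; for SPA the RMSE path, for CARS
#' the RMSECV/retained paths are available via [autoplot()] or the object
#' fields.
#'
#' @param x a `vs_selection`.
#' @param wavelengths optional nm axis to attach.
#' @param ... unused.
#' @export
tidy.vs_selection <- function(x, wavelengths = NULL, ...) {
  out <- tibble(index = x$indices)
  if (!is.null(wavelengths)) out$wavelength_nm <- wavelengths[x$indices]
  out
}

#' @rdname tidy.vs_selection
#' @export
glance.vs_selection <- function(x, ...) {
  if (x$method == "SPA") {
    tibble(method = "SPA", n_selected = length(x$indices),
           best_size = x$best_size, best_rmse = x$best_rmse)
  } else {
    tibble(method = "CARS", n_selected = length(x$indices),
           chosen_iteration = x$chosen_iteration,
           min_rmsecv = min(x$rmsecv_path, na.rm = TRUE))
  }
}
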