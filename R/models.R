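# Regression models (SVR wrapper; PLSR lives in pls.R, the 1D-CNN in cnn.R)
# and the evaluation contract shared by all of them.

#' Fit epsilon-insensitive support vector regression (RBF kernel)
#'
#' Features are standardized internally with training statistics; the
#' standardization is frozen into the model and reapplied at prediction
#' time. Residuals within `epsilon` of the target contribute zero loss.
#'
#' @param X predictor matrix.
#' @param y numeric response.
#' @param cost soft-margin cost C (default 10).
#' @param epsilon insensitive-tube half width (default 0.1).
#' @param gamma RBF kernel width; default `1 / ncol(X)` on the standardized
#'   features.
#' @return A `vs_svr` model supporting [predict()] and [glance()].
#' @export
fit_svr <- function(X, y, cost = 10, epsilon = 0.1, gamma = NULL) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  gamma <- gamma %||% (1 / ncol(X))
  # when every residual fits inside the epsilon tube (constant response or a
  # very wide tube) the solution is flat: no support vectors, predict the mean
  fit <- tryCatch(
    e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stopf("SVR fit failed: %s", conditionMessage(e))
    })
  structure(list(fit = fit, flat_value = if (is.null(fit)) mean(y),
                 center = center, scale = scale_,
                 cost = cost, epsilon = epsilon, gamma = gamma, VN = ncol(X)),
            class = c("vs_svr", "vs_model"))
}

#' @export
predict.vs_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(object$fit)) return(rep(object$flat_value, nrow(newdata)))
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  unname(predict(object$fit, Xs))
}

#' @export
print.vs_svr <- function(x, ...) {
  cat(sprintf("<vs_svr> RBF, C = %g, epsilon = %g, gamma = %g, %d predictors\n",
              x$cost, x$epsilon, x$gamma, x$VN))
  invisible(x)
}

#' Small grid search for SVR hyperparameters on a validation split
#'
#' @param X,y training data; an internal 80/20 SPXY split provides the
#'   validation fold.
#' @param cost,gamma_mult,epsilon candidate values; `gamma_mult` multiplies
#'   the default gamma `1/p`.
#' @return The best parameter combination as a one-row tibble with its
#'   validation RMSE.
#' @export
svr_tune <- function(X, y, cost = c(1, 10, 100),
                     gamma_mult = c(0.25, 1, 4), epsilon = c(0.05, 0.1)) {
  X <- as.matrix(X)
  sp <- spxy_split(X, y, train_fraction = 0.8)
  grid <- expand.grid(cost = cost, gamma_mult = gamma_mult,
                      epsilon = epsilon)
  grid$rmse <- vapply(seq_len(nrow(grid)), function(i) {
    m <- fit_svr(X[sp$train_ids, , drop = FALSE], y[sp$train_ids],
                 cost = grid$cost[i], epsilon = grid$epsilon[i],
                 gamma = grid$gamma_mult[i] / ncol(X))
    rmse(y[sp$test_ids], predict(m, X[sp$test_ids, , drop = FALSE]))
  }, numeric(1))
  as_tibble(grid[which.min(grid$rmse), , drop = FALSE])
}

#' Evaluate a fitted model: correlation coefficient and RMSE
#'
#' Predicts on `(X, y)` and scores with the Pearson correlation coefficient
#' R between predictions and observations and the root mean square error.
#' Zero variance in either vector makes R undefined and is an error.
#'
#' @param model a fitted `vs_model` (PLSR, SVR or CNN).
#' @param X predictor matrix.
#' @param y observed responses.
#' @return A one-row tibble with columns `r` and `rmse`.
#' @export
evaluate <- function(model, X, y) {
  stopifnot(inherits(model, "vs_model"))
  regression_metrics(y, predict(model, X))
}

#' Fit one model kind by name
#'
#' Dispatch helper used by the pipeline grid.
#'
#' @param kind `"PLSR"`, `"SVR"` or `"CNN"`.
#' @param X,y training data.
#' @param plsr_components PLSR latent variables.
#' @param svr_params list of [fit_svr()] arguments.
#' @param cnn_spec a [cnn_spec()].
#' @return A fitted `vs_model`.
#' @export
fit_model <- function(kind = c("PLSR", "SVR", "CNN"), X, y,
                      plsr_components = 3, svr_params = list(),
                      cnn_spec = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         PLSR = fit_plsr(X, y, components = min(plsr_components,
                                                nrow(X) - 1, ncol(X))),
         SVR = do.call(fit_svr, c(list(X = X, y = y), svr_params)),
         CNN = fit_cnn(X, y, spec = cnn_spec %||% cnn_spec()))
}
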