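# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; global RNG restored
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# derive a child seed < 2^31 from a base seed and a stage label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) + h * 7919L) %% 2147483587L
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

as_matrix_rows <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

# Pearson correlation between observed and predicted responses
pearson_r <- function(y, yhat) {
  if (sd(y) == 0 || sd(yhat) == 0) {
    stopf("correlation undefined: zero variance in %s",
          if (sd(y) == 0) "observed values" else "predictions")
  }
  cor(y, yhat)
}

# root mean square error, sqrt(sum((yhat - y)^2) / n)
rmse <- function(y, yhat) sqrt(mean((yhat - y)^2))

#' Regression metrics: correlation coefficient and RMSE
#'
#' Computes the two scores used throughout the package to judge vitality
#' models: the Pearson correlation coefficient R between predictions and
#' observed values, and the root mean square error
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (\hat y_i - y_i)^2 / n}}.
#'
#' @param y observed responses.
#' @param yhat predicted responses, same length as `y`.
#' @return A tibble with columns `r` and `rmse`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  tibble(r = pearson_r(y, yhat), rmse = rmse(y, yhat))
}
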