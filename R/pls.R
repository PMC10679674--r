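# Partial least squares regression (NIPALS), single response.
#
# Authored in-package because the wavelength selectors need direct access
# to the regression coefficient vector at each iteration, and so the latent
# decomposition is under test rather than behind an opaque call.

#' Fit partial least squares regression (NIPALS)
#'
#' Decomposes centred predictors and response into latent variables chosen
#' to maximise predictor-response covariance, then regresses through the
#' latent space. Predictors and response are centred internally; no
#' scaling.
#'
#' @param X predictor matrix (n x p).
#' @param y numeric response, length n.
#' @param components number of latent variables (default 3).
#' @return A `vs_plsr` model with `coefficients` (length p, original
#'   predictor scale), `intercept`, scores/loadings/weights, and the data
#'   centres. Supports [predict()], [tidy()], [glance()].
#' @export
fit_plsr <- function(X, y, components = 3) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (!is_count(components) || components >= n) {
    stopf("components must be a positive integer below the number of training rows (%d)", n)
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  if (sum(E^2) == 0) stopf("predictor matrix is constant; PLSR undefined")

  A <- components
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # residual response orthogonal to predictors
      A <- a - 1
      break
    }
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) { A <- a - 1; break }
    p_ <- crossprod(E, t_)[, 1] / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
  }
  if (A == 0) stopf("no usable PLS component could be extracted")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]

  # B = W (P'W)^-1 q maps centred X to centred y
  B <- tryCatch(W %*% solve(crossprod(P, W), q),
                error = function(e) stopf("PLS coefficient solve failed: rank-deficient loadings"))
  model <- list(coefficients = drop(B), intercept = y_center - sum(x_center * drop(B)),
                x_center = x_center, y_center = y_center,
                weights = W, loadings = P, scores = Tm, y_loadings = q,
                components = A, VN = p)
  class(model) <- c("vs_plsr", "vs_model")
  model
}

#' @export
predict.vs_plsr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
print.vs_plsr <- function(x, ...) {
  cat(sprintf("<vs_plsr> %d component(s), %d predictors\n", x$components, x$VN))
  invisible(x)
}

# k-fold cross-validated RMSE of a PLS model on (X, y); folds assigned
# round-robin over a permutation drawn from the current RNG stream
pls_rmsecv <- function(X, y, components, folds = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- rep(seq_len(folds), length.out = n)[sample.int(n)]
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    a <- min(components, sum(tr) - 1, ncol(X))
    m <- fit_plsr(X[tr, , drop = FALSE], y[tr], components = a)
    pred <- predict(m, X[!tr, , drop = FALSE])
    press <- press + sum((pred - y[!tr])^2)
  }
  sqrt(press / n)
}
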