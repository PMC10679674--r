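# PLSR, SVR, 1D-CNN and the evaluation contract

test_that("one-component univariate PLSR equals the least-squares line", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  y <- 3 + 2 * x[, 1] + rnorm(30, sd = 0.1)
  m <- fit_plsr(x, y, components = 1)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(m$intercept), unname(ols[1]), tolerance = 1e-10)
  expect_equal(unname(m$coefficients), unname(ols[2]), tolerance = 1e-10)
  expect_equal(predict(m, x), unname(fitted(lm(y ~ x))), tolerance = 1e-10)
})

test_that("PLSR with enough components is exact on a low-rank response", {
  set.seed(2)
  Tm <- matrix(rnorm(40 * 3), 40, 3)
  P <- matrix(rnorm(3 * 12), 3, 12)
  X <- Tm %*% P
  y <- Tm %*% c(1, -2, 0.5)
  m <- fit_plsr(X, drop(y), components = 3)
  expect_gte(cor(predict(m, X), drop(y)), 1 - 1e-8)
})

test_that("full-rank PLSR reproduces the multiple-regression solution", {
  set.seed(3)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- rnorm(6)
  m <- fit_plsr(X, y, components = 4)
  # independent oracle: pseudo-inverse (normal equations) solution
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_equal(unname(m$coefficients), drop(beta), tolerance = 1e-8)
  expect_error(fit_plsr(X, y, components = 6), "below the number")
})

test_that("SVR honours its epsilon-insensitive contract", {
  set.seed(4)
  X <- matrix(rnorm(25 * 3), 25, 3)
  # constant response: prediction constant within epsilon
  m_const <- fit_svr(X, rep(5, 25), epsilon = 0.1)
  expect_true(all(abs(predict(m_const, X) - 5) <= 0.1 + 1e-8))
  # huge epsilon: every residual inside the tube, flat solution
  y <- rnorm(25)
  m_flat <- fit_svr(X, y, epsilon = 100)
  expect_lt(sd(predict(m_flat, X)), 1e-8)
})

test_that("RBF SVR beats a linear fit on a quadratic response", {
  set.seed(5)
  x <- seq(-2, 2, length.out = 60)
  y <- x^2 + rnorm(60, sd = 0.05)
  tr <- seq(1, 60, by = 2); te <- seq(2, 60, by = 2)
  X <- matrix(x, ncol = 1)
  m <- fit_svr(X[tr, , drop = FALSE], y[tr])
  rmse_svr <- sqrt(mean((predict(m, X[te, , drop = FALSE]) - y[te])^2))
  ols <- lm(y ~ x, data = data.frame(x = x[tr], y = y[tr]))
  rmse_ols <- sqrt(mean((predict(ols, data.frame(x = x[te])) - y[te])^2))
  expect_lt(rmse_svr, rmse_ols)
})

test_that("the CNN forward pass and loss behave as specified", {
  set.seed(6)
  X <- matrix(rnorm(12 * 8), 12, 8)
  y <- rnorm(12)
  m <- fit_cnn(X, y, cnn_spec(epochs = 2, rng_seed = 1))
  pred <- predict(m, X[1:4, ])
  expect_length(pred, 4)
  expect_true(all(is.finite(pred)))
  expect_length(m$loss_curve, 2)
  expect_equal(mse_loss(c(1, 2), c(1, 4)), 2)
  expect_error(fit_cnn(X[, 1:3], y, cnn_spec(epochs = 1)),
               "receptive field")
})

test_that("the CNN can memorize a small sample when trained to convergence", {
  set.seed(7)
  X <- matrix(rnorm(8 * 8), 8, 8)
  y <- rnorm(8)
  m <- fit_cnn(X, y, cnn_spec(epochs = 3000, lr = 1e-3, rng_seed = 1))
  expect_lt(mse_loss(predict(m, X), y), 0.01)
})

test_that("CNN training is reproducible under a fixed seed", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  m1 <- fit_cnn(X, y, cnn_spec(epochs = 5, rng_seed = 11))
  m2 <- fit_cnn(X, y, cnn_spec(epochs = 5, rng_seed = 11))
  expect_equal(m1$loss_curve, m2$loss_curve, tolerance = 1e-12)
  expect_identical(m1$par$W1, m2$par$W1)
})

test_that("evaluation metrics match their textbook formulas", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(r = 1, rmse = 0))
  expect_equal(regression_metrics(c(1, 5), c(2, 4))$rmse, 1)
  set.seed(9)
  y <- rnorm(40); yhat <- y + rnorm(40, sd = 0.5)
  m <- regression_metrics(y, yhat)
  # two-pass oracle
  r_o <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  expect_equal(m$r, r_o, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(sum((yhat - y)^2) / 40), tolerance = 1e-12)
  # invariant to permutation of sample order
  perm <- sample(40)
  expect_equal(regression_metrics(y[perm], yhat[perm]), m)
  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("all three models beat the train-mean baseline on planted data", {
  ds <- simulate_dataset(small_planted_config(rng_seed = 10))
  sp <- dataset_spectra(ds)
  y <- sp$vitality$vitality_cm
  spl <- spxy_split(sp$spectra, y, 0.7)
  tr <- spl$train_ids; te <- spl$test_ids
  idx <- unlist(ds$truth$informative_band_indices)
  Xtr <- sp$spectra[tr, idx]; Xte <- sp$spectra[te, idx]
  base_rmse <- sqrt(mean((y[te] - mean(y[tr]))^2))
  for (kind in c("PLSR", "SVR", "CNN")) {
    m <- fit_model(kind, Xtr, y[tr],
                   cnn_spec = cnn_spec(epochs = 30, lr = 1e-3, rng_seed = 2))
    expect_lt(evaluate(m, Xte, y[te])$rmse, base_rmse)
  }
})
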