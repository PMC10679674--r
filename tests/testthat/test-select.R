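# Wavelength selection: SPA and CARS

test_that("SPA on orthogonal columns selects in norm order", {
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  X <- Q %*% diag(c(3, 2, 1))
  y <- rowSums(X)
  Xv <- X + rnorm(36, sd = 1e-8)
  sel <- spa_select(X, y, Xv, y, max_vars = 3, starts = 1)
  # projection removes nothing between orthogonal columns; norms decide
  expect_equal(sel$chains[[1]], c(1L, 2L, 3L))
  expect_equal(sel$indices, 1:3)
})

test_that("an exact duplicate of a selected column is never selected", {
  set.seed(2)
  X <- matrix(rnorm(20 * 5), 20, 5)
  X <- cbind(X, X[, 2])  # column 6 duplicates column 2
  y <- X[, 2] + 0.5 * X[, 4] + rnorm(20, sd = 0.01)
  sel <- spa_select(X, y, X, y, max_vars = 5, starts = 2)
  expect_false(6 %in% sel$chains[[1]])
})

test_that("SPA result is invariant to duplicating a non-selected column", {
  set.seed(3)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- 2 * X[, 1] - X[, 5] + rnorm(25, sd = 0.01)
  Xv <- matrix(rnorm(10 * 6), 10, 6)
  yv <- 2 * Xv[, 1] - Xv[, 5] + rnorm(10, sd = 0.01)
  s1 <- spa_select(X, y, Xv, yv, max_vars = 3)
  stray <- setdiff(1:6, s1$indices)[1]
  s2 <- spa_select(cbind(X, X[, stray]), y, cbind(Xv, Xv[, stray]), yv,
                   max_vars = 3)
  expect_equal(s2$indices, s1$indices)
})

test_that("SPA matches the exhaustive best two-wavelength subset", {
  set.seed(4)
  n <- 20; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  # give the informative columns the largest norms so greedy chains cover them
  X[, 2] <- 3 * X[, 2]; X[, 5] <- 3 * X[, 5]
  y <- 1.5 * X[, 2] - X[, 5] + rnorm(n, sd = 1e-4)
  Xv <- matrix(rnorm(12 * p), 12, p)
  Xv[, 2] <- 3 * Xv[, 2]; Xv[, 5] <- 3 * Xv[, 5]
  yv <- 1.5 * Xv[, 2] - Xv[, 5] + rnorm(12, sd = 1e-4)

  sel <- spa_select(X, y, Xv, yv, max_vars = 3)
  spa2 <- spa_best_at_size(sel, 2)

  # independent oracle: all C(8,2) subsets by multiple linear regression
  combos <- t(combn(p, 2))
  oracle <- apply(combos, 1, function(cols) {
    fit <- lm.fit(cbind(1, X[, cols]), y)
    pred <- cbind(1, Xv[, cols]) %*% fit$coefficients
    sqrt(mean((yv - pred)^2))
  })
  expect_lt(abs(spa2$rmse - min(oracle)), 1e-6)
  expect_equal(spa2$indices, sort(combos[which.min(oracle), ]))
})

test_that("SPA-selected columns are pairwise linearly independent", {
  set.seed(5)
  X <- matrix(rnorm(30 * 10), 30, 10)
  X[, 7] <- X[, 3]  # plant an exact twin
  y <- rnorm(30)
  sel <- spa_select(X, y, X, y, max_vars = 6)
  G <- crossprod(X[, sel$indices])
  expect_gt(det(G), 0)
  expect_false(all(c(3, 7) %in% sel$indices))
})

test_that("CARS paths honour the exponential schedule contract", {
  set.seed(6)
  X <- matrix(rnorm(40 * 50), 40, 50)
  y <- X[, 10] - 2 * X[, 30] + rnorm(40, sd = 0.05)
  sel <- cars_select(X, y, n_mc = 30, rng_seed = 7)
  expect_equal(sel$retained_path[1], 50)
  expect_true(all(diff(sel$retained_path) <= 0))
  expect_equal(sel$chosen_iteration, which.min(sel$rmsecv_path))
  expect_equal(sel$indices, sel$sets[[sel$chosen_iteration]])
  expect_true(all(sel$indices >= 1 & sel$indices <= 50))
  expect_false(any(duplicated(sel$indices)))
})

test_that("CARS is bit-reproducible under a fixed seed", {
  set.seed(8)
  X <- matrix(rnorm(30 * 40), 30, 40)
  y <- X[, 5] + rnorm(30, sd = 0.1)
  a <- cars_select(X, y, n_mc = 25, rng_seed = 123)
  b <- cars_select(X, y, n_mc = 25, rng_seed = 123)
  expect_identical(a$indices, b$indices)
  expect_identical(a$rmsecv_path, b$rmsecv_path)
  expect_identical(a$coef_paths, b$coef_paths)
})

test_that("CARS finds the planted features and a near-zero RMSECV without noise", {
  ds <- simulate_dataset(small_planted_config(noise_sd = 0, scatter_sd = 0,
                                              offset_sd = 0, rng_seed = 9))
  sp <- dataset_spectra(ds)
  sel <- cars_select(sp$spectra, sp$vitality$vitality_cm, n_mc = 50,
                     rng_seed = 10)
  expect_lt(min(sel$rmsecv_path, na.rm = TRUE), 1e-4)
  rec <- bands_recovered(sel, ds$truth$informative_band_indices)
  expect_true(any(rec))
})

test_that("CARS recovers planted features across seeds at desk scale", {
  ds <- simulate_dataset(small_planted_config(rng_seed = 12))
  sp <- dataset_spectra(ds)
  hits <- vapply(1:5, function(s) {
    sel <- cars_select(sp$spectra, sp$vitality$vitality_cm, n_mc = 50,
                       rng_seed = s)
    all(bands_recovered(sel, ds$truth$informative_band_indices))
  }, logical(1))
  expect_gte(sum(hits), 4)
})
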