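test_that("SNV standardizes each spectrum and is idempotent", {
  expect_equal(drop(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(8 * 30, mean = 5, sd = 2), 8, 30)
  Z <- snv(X)
  expect_equal(rowMeans(Z), rep(0, 8), tolerance = 1e-10)
  expect_equal(apply(Z, 1, sd), rep(1, 8), tolerance = 1e-10)
  expect_equal(snv(Z), Z, tolerance = 1e-12)
  Xc <- X; Xc[3, ] <- 7
  expect_error(snv(Xc), "row\\(s\\) 3")
})

test_that("MSC inverts the affine scatter model against its reference", {
  set.seed(2)
  ref <- runif(25, 0.2, 0.9)
  expect_equal(drop(msc(matrix(ref, 1), ref)), ref)
  expect_equal(drop(msc(matrix(2 * ref + 3, 1), ref)), ref, tolerance = 1e-12)
  # corrected rows regress on the reference with slope 1, intercept 0
  X <- t(vapply(1:6, function(i) runif(1, 0.5, 2) * ref +
                  runif(1, -0.3, 0.3) + rnorm(25, sd = 0.01), numeric(25)))
  Z <- msc(X, ref)
  for (i in 1:6) {
    co <- coef(lm(Z[i, ] ~ ref))
    expect_equal(unname(co[1]), 0, tolerance = 1e-8)
    expect_equal(unname(co[2]), 1, tolerance = 1e-8)
  }
  # exact affine rows invert exactly
  Xe <- rbind(1.7 * ref - 0.2, 0.4 * ref + 0.9)
  Ze <- msc(Xe, ref)
  expect_equal(Ze[1, ], ref, tolerance = 1e-8)
  expect_equal(Ze[2, ], ref, tolerance = 1e-8)
  expect_error(msc(X, rep(1, 25)), "zero spread")
})

test_that("MSC with the mean-row reference leaves the mean row fixed", {
  set.seed(3)
  X <- matrix(runif(5 * 20), 5, 20)
  X <- rbind(X, colMeans(X))
  Z <- msc(X)
  expect_equal(Z[6, ], colMeans(X), tolerance = 1e-10)
})

test_that("Savitzky-Golay reproduces polynomials and matches a windowed fit", {
  x <- (1:30)^2 - 3 * (1:30) + 2  # quadratic
  sm <- sg_smooth(matrix(x, 1), window = 5, polyorder = 2)
  expect_equal(drop(sm), x, tolerance = 1e-8)
  expect_equal(drop(sg_smooth(matrix(rep(4, 20), 1), 7, 2)), rep(4, 20))

  # centre value equals an explicit local polynomial least-squares fit
  set.seed(4)
  row <- rnorm(21)
  sm2 <- drop(sg_smooth(matrix(row, 1), window = 7, polyorder = 2))
  i <- 11
  wnd <- (i - 3):(i + 3)
  fit <- lm(row[wnd] ~ poly(wnd, 2, raw = TRUE))
  expect_equal(sm2[i], unname(fitted(fit)[4]), tolerance = 1e-8)

  expect_error(sg_smooth(matrix(rnorm(10), 1), window = 4, polyorder = 2), "odd")
  expect_error(sg_smooth(matrix(rnorm(10), 1), window = 3, polyorder = 3), "odd")
  expect_error(sg_smooth(matrix(rnorm(10), 1), window = 11, polyorder = 2),
               "exceeds")
})

test_that("SG smoothing does not increase total squared second difference", {
  set.seed(5)
  for (i in 1:5) {
    row <- sin(seq(0, 4 * pi, length.out = 60)) + rnorm(60, sd = 0.3)
    sm <- drop(sg_smooth(matrix(row, 1), window = 9, polyorder = 2))
    ssd <- function(v) sum(diff(v, differences = 2)^2)
    expect_lte(ssd(sm), ssd(row))
  }
})

test_that("per-row transforms commute with wavelength re-indexing", {
  set.seed(6)
  X <- matrix(runif(4 * 15, 0.2, 0.8), 4, 15)
  perm <- sample(15)
  expect_equal(snv(X)[, perm], snv(X[, perm]))
  ref <- colMeans(X)
  expect_equal(msc(X, ref)[, perm], msc(X[, perm], ref[perm]))
})

test_that("fitted pretreatments freeze training statistics for the test fold", {
  set.seed(7)
  Xtr <- matrix(runif(10 * 20), 10, 20)
  Xte <- matrix(runif(4 * 20), 4, 20)
  fit <- preprocess_fit(Xtr, "MSC")
  expect_equal(fit$reference, colMeans(Xtr))
  # applying to test uses the training reference, not the test mean
  expect_equal(preprocess_apply(fit, Xte), msc(Xte, colMeans(Xtr)))
  # SG/SNV are row-local but share the API
  expect_equal(preprocess_apply(preprocess_fit(Xtr, "SNV"), Xte), snv(Xte))
  expect_equal(preprocess_apply(preprocess_fit(Xtr, "SG"), Xte),
               sg_smooth(Xte, 11, 2))
})
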