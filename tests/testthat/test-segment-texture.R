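# Segmentation, PA/MIoU, GLCM texture

test_that("segmentation recovers the plate layout and labels row-major", {
  ds <- simulate_dataset(small_planted_config(rng_seed = 1))
  cube <- correct_reflectance(ds$plates[[1]])
  img <- apply(cube$S, c(1, 2), mean)
  m <- segment_plate(img)
  expect_equal(max(m), 25)
  # row-major renumbering matches the ground-truth layout
  expect_gte(pixel_accuracy(m, ds$masks[[1]]), 95)
  agree <- mean(m[ds$masks[[1]] > 0] == ds$masks[[1]][ds$masks[[1]] > 0])
  expect_gte(agree, 0.95)
})

test_that("blank images are rejected", {
  expect_error(segment_plate(matrix(0.5, 10, 10)), "constant")
})

test_that("8-connectivity keeps diagonals together and gaps apart", {
  img <- matrix(0, 12, 12)
  img[2:4, 2:4] <- 1
  img[5, 5] <- 1  # diagonally adjacent to the block: same component
  img[8:10, 8:10] <- 1  # separated: own component
  lab <- vitaspec:::label_components(img > 0)
  expect_equal(max(lab), 2)
  expect_equal(lab[5, 5], lab[3, 3])
  # two blobs separated by a 1-px background gap remain distinct
  img2 <- matrix(0, 10, 14)
  img2[3:7, 2:6] <- 1
  img2[3:7, 8:12] <- 1  # column 7 stays background
  m2 <- segment_plate(img2)
  expect_equal(max(m2), 2)
  expect_true(all(m2[, 2:6][img2[, 2:6] > 0] == 1))
  expect_true(all(m2[, 8:12][img2[, 8:12] > 0] == 2))
})

test_that("pixel accuracy and mean IoU match closed forms and brute force", {
  truth <- matrix(0L, 8, 8); truth[, 1:4] <- 1L  # half foreground
  pred_all_bg <- matrix(0L, 8, 8)
  expect_equal(pixel_accuracy(truth, truth), 100)
  expect_equal(mean_iou(truth, truth), 100)
  expect_equal(pixel_accuracy(pred_all_bg, truth), 50)
  # IoU_bg = 0.5, IoU_fg = 0 -> 25 %
  expect_message(miou <- mean_iou(pred_all_bg, truth), NA)
  expect_equal(miou, 25)

  set.seed(2)
  p <- matrix(rbinom(256, 1, 0.4), 16, 16)
  t_ <- matrix(rbinom(256, 1, 0.5), 16, 16)
  # brute-force confusion tally
  n <- matrix(0, 2, 2)
  for (i in 1:16) for (j in 1:16) {
    n[p[i, j] + 1, t_[i, j] + 1] <- n[p[i, j] + 1, t_[i, j] + 1] + 1
  }
  pa_oracle <- (n[1, 1] + n[2, 2]) / sum(n) * 100
  iou_oracle <- mean(c(n[1, 1] / (sum(n[1, ]) + sum(n[, 1]) - n[1, 1]),
                       n[2, 2] / (sum(n[2, ]) + sum(n[, 2]) - n[2, 2]))) * 100
  expect_equal(pixel_accuracy(p, t_), pa_oracle)
  expect_equal(mean_iou(p, t_), iou_oracle)
  # symmetric under swapping prediction and truth for binary masks
  expect_equal(pixel_accuracy(p, t_), pixel_accuracy(t_, p))
  expect_equal(mean_iou(p, t_), mean_iou(t_, p))
  expect_error(pixel_accuracy(p, t_[1:8, ]), "shapes differ")
})

test_that("GLCM reproduces the hand-counted 2x2 example", {
  img <- rbind(c(0, 0), c(1, 1))
  p <- glcm(img, levels = 2, distance = 1, angle = 0, symmetric = FALSE)
  expect_equal(p, rbind(c(0.5, 0), c(0, 0.5)), ignore_attr = TRUE)
  f <- texture_features(p)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)
})

test_that("GLCM normalization, constant patches and offset invariance", {
  set.seed(3)
  patch <- matrix(runif(64), 8, 8)
  p <- glcm(patch, levels = 8)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # constant patch: single entry 1; degenerate correlation warns
  pc <- glcm(matrix(5, 4, 4), levels = 8)
  expect_equal(sum(pc == 1), 1)
  expect_warning(fc <- texture_features(pc), "zero variance")
  expect_equal(unname(fc["contrast"]), 0)
  expect_equal(unname(fc["energy"]), 1)
  expect_equal(unname(fc["entropy"]), 0)
  # gray-offset invariance (level edges span the patch range)
  expect_equal(glcm(patch + 3.7, levels = 8), glcm(patch, levels = 8))
  expect_error(glcm(matrix(1, 1, 1), levels = 4), "no valid pixel pairs")
})

test_that("texture features match an independent double-loop oracle", {
  set.seed(4)
  for (ang in c(0, 45, 90, 135)) {
    patch <- matrix(runif(60), 6, 10)
    off <- vitaspec:::.glcm_offset(ang, 1L)
    p <- glcm(patch, levels = 6, distance = 1, angle = ang, symmetric = TRUE)
    oracle <- brute_glcm_features(patch, 6, off[1], off[2], symmetric = TRUE)
    expect_equal(texture_features(p), oracle, tolerance = 1e-12)
  }
})

test_that("feature invariants hold on random patches", {
  set.seed(5)
  for (i in 1:10) {
    patch <- matrix(runif(49), 7, 7)
    f <- texture_features(glcm(patch, levels = 8))
    expect_gte(f[["contrast"]], 0)
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_gte(f[["entropy"]], 0)
    expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
  }
})

test_that("the texture matrix has band-major blocks of four features", {
  ds <- simulate_dataset(small_planted_config(rng_seed = 6))
  cube <- correct_reflectance(ds$plates[[1]])
  bands <- c(10, 40, 70, 100, 5, 55, 80, 110, 25, 90)
  tm <- seed_texture_matrix(cube, ds$masks[[1]], bands)
  expect_equal(dim(tm), c(25, 40))
  expect_match(colnames(tm)[1], "contrast")
  expect_match(colnames(tm)[4], "entropy")
  # permuting the band list permutes the column blocks correspondingly
  perm <- c(3, 1, 2, 4:10)
  tm2 <- seed_texture_matrix(cube, ds$masks[[1]], bands[perm])
  blocks <- function(m, k) m[, (k - 1) * 4 + 1:4]
  for (k in seq_along(perm)) {
    expect_equal(blocks(tm2, k), blocks(tm, perm[k]), ignore_attr = TRUE)
  }
  # a degenerate (single-pixel) seed is reported by name
  bad_mask <- ds$masks[[1]]
  bad_mask[bad_mask == 2L] <- 0L
  bad_mask[1, 1] <- 2L
  expect_error(seed_texture_matrix(cube, bad_mask, bands[1:2]), "seed 2")
})

test_that("seed texture contrast tracks the planted texture latent", {
  ds <- simulate_dataset(sim_config(n_plates = 4, n_bands = 60, rng_seed = 9))
  cubes <- lapply(ds$plates, correct_reflectance)
  texm <- do.call(rbind, mapply(function(cu, m)
    seed_texture_matrix(cu, m, c(20, 40)), cubes, ds$masks, SIMPLIFY = FALSE))
  cm <- rowMeans(texm[, grep("contrast", colnames(texm)), drop = FALSE])
  expect_gt(cor(cm, ds$truth$texture_latent, method = "spearman"), 0.8)
})
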