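test_that("noiseless simulation is exactly inverted by calibration", {
  cfg <- small_planted_config(n_plates = 1, noise_sd = 0, scatter_sd = 0,
                              offset_sd = 0, rng_seed = 1)
  ds <- simulate_dataset(cfg)
  cube <- correct_reflectance(ds$plates[[1]])
  sp <- extract_seed_spectra(cube, ds$masks[[1]])
  expect_equal(sp, ds$truth$spectra_true[1:25, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- small_planted_config(rng_seed = 42)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$plates[[1]]$O, ds2$plates[[1]]$O)
  expect_identical(ds1$vitality, ds2$vitality)
  expect_identical(ds1$truth$texture_latent, ds2$truth$texture_latent)
})

test_that("plate, mask and vitality-record counts follow the configuration", {
  ds <- simulate_dataset(small_planted_config(rng_seed = 3))
  expect_length(ds$plates, 2)
  expect_length(ds$masks, 2)
  expect_true(all(vapply(ds$masks, max, integer(1)) == 25L))
  expect_equal(nrow(ds$vitality), 50)
  expect_true(all(ds$vitality$vitality_cm > 0))
  expect_true(all(diff(ds$wavelengths) > 0))
  for (idx in ds$truth$informative_band_indices) {
    expect_true(all(idx >= 1 & idx <= ds$config$n_bands))
  }
})

test_that("a steeper planted slope strictly strengthens the vitality-band correlation", {
  cors <- vapply(c(0.004, 0.010, 0.016), function(sl) {
    ab <- small_absorption_bands()
    ab$slope_per_cm[2] <- sl
    ds <- simulate_dataset(small_planted_config(absorption_bands = ab,
                                                noise_sd = 0.002,
                                                scatter_sd = 0.005,
                                                offset_sd = 0.002,
                                                rng_seed = 5))
    center_band <- which.min(abs(ds$wavelengths - ab$center_nm[2]))
    sp <- dataset_spectra(ds)
    abs(cor(sp$spectra[, center_band], sp$vitality$vitality_cm))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("ordinary least squares on the planted bands recovers vitality at low noise", {
  ds <- simulate_dataset(small_planted_config(noise_sd = 0.001,
                                              scatter_sd = 0.002,
                                              offset_sd = 0.001,
                                              rng_seed = 8))
  sp <- dataset_spectra(ds)
  centers <- vapply(ds$truth$informative_band_indices,
                    function(idx) idx[ceiling(length(idx) / 2)], integer(1))
  fit <- lm(sp$vitality$vitality_cm ~ sp$spectra[, centers])
  r <- cor(fitted(fit), sp$vitality$vitality_cm)
  expect_gte(r, 0.99)
})

test_that("write_fixture writes the expected files and round-trips the cubes", {
  ds <- simulate_dataset(small_planted_config(rng_seed = 11))
  out <- withr::local_tempdir()
  manifest <- write_fixture(ds, out)
  # 2 raw + 2 hdr + 2 masks + 1 csv
  expect_equal(nrow(manifest), 7)
  expect_setequal(manifest$file,
                  c("plate01.raw", "plate01.hdr", "plate02.raw", "plate02.hdr",
                    "mask01.png", "mask02.png", "vitality.csv"))
  back <- read_envi(file.path(out, "plate01"))
  cube <- correct_reflectance(ds$plates[[1]])
  expect_identical(back$cube, cube$S)
  expect_equal(back$wavelengths, ds$wavelengths)
  expect_equal(read_mask(file.path(out, "mask01.png")), ds$masks[[1]],
               ignore_attr = TRUE)
  vit <- read.csv(file.path(out, "vitality.csv"))
  expect_equal(vit$vitality_cm, ds$vitality$vitality_cm)
})

test_that("fixture checksums change iff the configuration changes", {
  ds_a <- simulate_dataset(small_planted_config(rng_seed = 21))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  m1 <- write_fixture(ds_a, out1)
  m2 <- write_fixture(ds_a, out2)
  expect_equal(m1$md5, m2$md5)  # identical config -> identical bytes
  ds_b <- simulate_dataset(small_planted_config(rng_seed = 22))
  out3 <- withr::local_tempdir()
  m3 <- write_fixture(ds_b, out3)
  expect_false(any(m3$md5[m3$file == "plate01.raw"] ==
                     m1$md5[m1$file == "plate01.raw"]))
})
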