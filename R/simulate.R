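# Synthetic hyperspectral plate generator.
#
# Emulates the structure the downstream analysis assumes: plates of seeds
# imaged by a VNIR line-scan camera (520 bands, ~391-1042 nm), a vitality
# response (seedling height, cm) expressed through Gaussian absorption
# features whose depth is affine in vitality, per-seed multiplicative
# scatter and additive offset, pixel noise, and intra-seed texture whose
# contrast tracks a latent that is (partially) coupled to vitality.

#' Configuration for the synthetic plate generator
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 8 plates of 25 seeds (200 seeds total), 520 bands from 391 nm in steps
#' chosen so the last band falls near 1042 nm, vitality ~ N(10, 2) cm
#' truncated positive, and three planted absorption features (one centred
#' at 711 nm).
#'
#' @param n_plates number of plates.
#' @param seeds_per_plate seeds per plate, arranged on a near-square grid
#'   (25 gives 5 x 5).
#' @param n_bands number of spectral bands.
#' @param wavelength_start_nm first band centre (nm).
#' @param wavelength_step_nm band spacing (nm). The default 1.254 puts band
#'   520 at ~1041.8 nm.
#' @param vitality_mean_cm,vitality_sd_cm mean / sd of seedling height (cm).
#' @param absorption_bands data frame with columns `center_nm`, `width_nm`
#'   (Gaussian sigma), `base` (depth at vitality 0) and `slope_per_cm`
#'   (depth change per cm of vitality). These are the planted informative
#'   features.
#' @param scatter_sd sd of the per-seed multiplicative scatter factor
#'   (mean 1).
#' @param offset_sd sd of the per-seed additive baseline offset.
#' @param noise_sd sd of iid per-pixel, per-band Gaussian noise
#'   (reflectance units).
#' @param texture_sd multiplicative amplitude (relative sd) of the
#'   intra-seed pixel texture field.
#' @param texture_roughness_gain how strongly the texture latent t controls
#'   the field's roughness: the iid fraction of the field is
#'   `plogis(texture_roughness_gain * t)`, so GLCM contrast increases
#'   monotonically with t. (Roughness, not amplitude, carries the latent:
#'   co-occurrence features quantized over the patch range are invariant to
#'   pure amplitude scaling.)
#' @param texture_coupling correlation in `[0,1]` between the texture latent
#'   and (standardised) vitality when `fusion_sensitive = FALSE`.
#' @param fusion_sensitive if `TRUE`, vitality is composed from a spectral
#'   latent and the texture latent with nonzero weights, so image texture
#'   carries information the spectra alone lack.
#' @param fusion_weights length-3 weights (spectral, texture, noise) used in
#'   `fusion_sensitive` mode.
#' @param plate_px plate image side length in pixels.
#' @param white_level,dark_level digital-number levels of the white and dark
#'   reference frames (arbitrary DN units).
#' @param rng_seed integer seed; everything downstream of it is
#'   deterministic.
#' @return A `vs_sim_config` list.
#' @export
sim_config <- function(n_plates = 8,
                       seeds_per_plate = 25,
                       n_bands = 520,
                       wavelength_start_nm = 391,
                       wavelength_step_nm = 1.254,
                       vitality_mean_cm = 10,
                       vitality_sd_cm = 2,
                       absorption_bands = default_absorption_bands(),
                       scatter_sd = 0.03,
                       offset_sd = 0.01,
                       noise_sd = 0.01,
                       texture_sd = 0.08,
                       texture_roughness_gain = 1.2,
                       texture_coupling = 0.6,
                       fusion_sensitive = FALSE,
                       fusion_weights = c(spectral = 0.75, texture = 0.6,
                                          noise = 0.2),
                       plate_px = 80,
                       white_level = 4000,
                       dark_level = 120,
                       rng_seed = 42) {
  cfg <- list(n_plates = n_plates, seeds_per_plate = seeds_per_plate,
              n_bands = n_bands, wavelength_start_nm = wavelength_start_nm,
              wavelength_step_nm = wavelength_step_nm,
              vitality_mean_cm = vitality_mean_cm,
              vitality_sd_cm = vitality_sd_cm,
              absorption_bands = as.data.frame(absorption_bands),
              scatter_sd = scatter_sd, offset_sd = offset_sd,
              noise_sd = noise_sd,
              texture_sd = texture_sd,
              texture_roughness_gain = texture_roughness_gain,
              texture_coupling = texture_coupling,
              fusion_sensitive = fusion_sensitive,
              fusion_weights = fusion_weights,
              plate_px = plate_px,
              white_level = white_level, dark_level = dark_level,
              rng_seed = rng_seed)
  class(cfg) <- "vs_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Planted absorption features used by default
#'
#' Three Gaussian absorption features; 711 nm is the band used in worked
#' texture examples throughout the package. Slopes are chosen so the
#' effective depth signal (baseline reflectance times slope) is about equal
#' across the three features — no planted feature dominates the others.
#' @return Data frame with columns `center_nm`, `width_nm`, `base`,
#'   `slope_per_cm`.
#' @export
default_absorption_bands <- function() {
  data.frame(center_nm = c(500, 711, 950),
             width_nm = c(14, 12, 16),
             base = c(0.06, 0.08, 0.05),
             slope_per_cm = c(0.015, 0.012, 0.011))
}

validate_sim_config <- function(cfg) {
  for (f in c("n_plates", "seeds_per_plate", "n_bands", "plate_px")) {
    if (!is_count(cfg[[f]])) stopf("sim config: '%s' must be a positive integer", f)
  }
  if (cfg$wavelength_step_nm <= 0) {
    stopf("sim config: wavelength step must be positive (degenerate axis)")
  }
  if (cfg$vitality_sd_cm < 0 || cfg$vitality_mean_cm <= 0) {
    stopf("sim config: vitality distribution must have positive mean and non-negative sd")
  }
  ab <- cfg$absorption_bands
  need <- c("center_nm", "width_nm", "base", "slope_per_cm")
  if (!all(need %in% names(ab)) || nrow(ab) < 1) {
    stopf("sim config: absorption_bands needs columns %s", paste(need, collapse = ", "))
  }
  if (cfg$texture_coupling < 0 || cfg$texture_coupling > 1) {
    stopf("sim config: texture_coupling must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Wavelength axis of a simulator configuration
#' @param config a `vs_sim_config`.
#' @return Numeric vector of band centres (nm), strictly increasing.
#' @export
sim_wavelengths <- function(config) {
  config$wavelength_start_nm +
    (seq_len(config$n_bands) - 1) * config$wavelength_step_nm
}

# centre and scale a pixel field to mean 0, sample sd 1 (constant -> zeros)
.unit_field <- function(x) {
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

# smooth baseline reflectance profile of a seed across the VNIR range
.baseline_reflectance <- function(wl) {
  0.45 + 0.30 * stats::plogis((wl - 620) / 140)
}

# analytic seed reflectance r(lambda) for vitality-equivalent value v (cm):
# r(l) = B(l) * (1 - sum_k alpha_k(v) * exp(-(l - mu_k)^2 / (2 sigma_k^2)))
.seed_reflectance <- function(wl, v, ab) {
  depth <- rep(0, length(wl))
  for (k in seq_len(nrow(ab))) {
    alpha <- ab$base[k] + ab$slope_per_cm[k] * v
    depth <- depth + alpha * exp(-(wl - ab$center_nm[k])^2 / (2 * ab$width_nm[k]^2))
  }
  .baseline_reflectance(wl) * (1 - depth)
}

# indices (1-based) of bands within each absorption feature's FWHM
.informative_bands <- function(wl, ab) {
  lapply(seq_len(nrow(ab)), function(k) {
    half_width <- ab$width_nm[k] * sqrt(2 * log(2))
    which(abs(wl - ab$center_nm[k]) <= half_width)
  })
}

# seed centres and elliptical footprints on a plate grid
.plate_layout <- function(cfg) {
  spp <- cfg$seeds_per_plate
  n_rows <- max(1L, round(sqrt(spp)))
  n_cols <- ceiling(spp / n_rows)
  cell <- cfg$plate_px / max(n_rows, n_cols)
  a <- max(2.2, 0.30 * cell)  # semi-axis along columns
  b <- max(1.8, 0.22 * cell)  # semi-axis along rows
  pos <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  pos <- pos[order(pos$row, pos$col), , drop = FALSE][seq_len(spp), , drop = FALSE]
  cy <- (pos$row - 0.5) * (cfg$plate_px / n_rows)
  cx <- (pos$col - 0.5) * (cfg$plate_px / n_cols)
  list(n_rows = n_rows, n_cols = n_cols, row = pos$row, col = pos$col,
       cy = cy, cx = cx, a = a, b = b)
}

#' Generate a synthetic hyperspectral plate dataset
#'
#' Produces, per plate, a raw digital-number cube `O` plus white `X` and
#' dark `Y` reference cubes such that reflectance calibration
#' `S = (O - Y) / (X - Y)` recovers the intended reflectance; ground-truth
#' label masks; and a vitality table. The planted signal is recoverable:
#' regressing vitality on the reflectance of the planted bands succeeds at
#' low noise, which is the oracle all downstream recovery tests build on.
#'
#' @param config a [sim_config()].
#' @return A `vs_dataset` list with elements `plates` (list of
#'   `vs_raw_capture`: `O`, `X`, `Y` arrays), `wavelengths`, `masks` (list
#'   of integer label matrices, labels 1..seeds row-major), `vitality`
#'   (tibble: seed_id, plate, row, col, vitality_cm), `truth` (list:
#'   `spectra_true` seeds x bands analytic reflectance,
#'   `informative_band_indices` list per planted feature, `texture_latent`,
#'   `spectral_latent`, `scatter`, `offset`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$rng_seed, {
    wl <- sim_wavelengths(cfg)
    n_seeds <- cfg$n_plates * cfg$seeds_per_plate
    ab <- cfg$absorption_bands

    # latent structure
    if (cfg$fusion_sensitive) {
      w <- cfg$fusion_weights / sqrt(sum(cfg$fusion_weights^2))
      z_s <- rnorm(n_seeds); z_t <- rnorm(n_seeds); z_e <- rnorm(n_seeds)
      z_v <- w[1] * z_s + w[2] * z_t + w[3] * z_e
      vitality <- cfg$vitality_mean_cm + cfg$vitality_sd_cm * z_v
      v_spec <- cfg$vitality_mean_cm + cfg$vitality_sd_cm * z_s
      t_lat <- z_t
    } else {
      z_v <- rnorm(n_seeds)
      vitality <- cfg$vitality_mean_cm + cfg$vitality_sd_cm * z_v
      v_spec <- vitality
      rho <- cfg$texture_coupling
      t_lat <- rho * z_v + sqrt(1 - rho^2) * rnorm(n_seeds)
    }
    # truncate vitality strictly positive (heights cannot be negative)
    low <- pmax(0.2, cfg$vitality_mean_cm - 4 * cfg$vitality_sd_cm)
    vitality <- pmax(vitality, low)
    v_spec <- pmax(v_spec, low)

    scatter <- 1 + cfg$scatter_sd * rnorm(n_seeds)
    offset <- cfg$offset_sd * rnorm(n_seeds)
    # texture latent -> iid (rough) fraction of the intra-seed field
    rough_frac <- stats::plogis(cfg$texture_roughness_gain * t_lat)

    spectra_true <- t(vapply(v_spec, function(v) .seed_reflectance(wl, v, ab),
                             numeric(cfg$n_bands)))

    layout <- .plate_layout(cfg)
    px <- cfg$plate_px
    bg_refl <- 0.05

    plates <- vector("list", cfg$n_plates)
    masks <- vector("list", cfg$n_plates)
    rows_tbl <- vector("list", cfg$n_plates)

    coord_r <- matrix(seq_len(px), px, px)
    coord_c <- matrix(seq_len(px), px, px, byrow = TRUE)

    for (p in seq_len(cfg$n_plates)) {
      seed_idx <- (p - 1) * cfg$seeds_per_plate + seq_len(cfg$seeds_per_plate)
      mask <- matrix(0L, px, px)
      S <- array(bg_refl, c(px, px, cfg$n_bands))
      for (j in seq_len(cfg$seeds_per_plate)) {
        i <- seed_idx[j]
        inside <- ((coord_r - layout$cy[j]) / layout$b)^2 +
          ((coord_c - layout$cx[j]) / layout$a)^2 <= 1
        pix <- which(inside)
        mask[pix] <- j
        # intra-seed texture: a mix of a smooth directional gradient and an
        # iid field; the latent controls the iid (rough) fraction, so GLCM
        # contrast tracks it. The field is centred and scaled within the
        # seed so the mask-mean spectrum equals the analytic r_i(lambda)
        # exactly and the amplitude is common to all seeds.
        phi <- runif(1, 0, 2 * pi)
        smooth <- cos(phi) * (coord_r[pix] - layout$cy[j]) +
          sin(phi) * (coord_c[pix] - layout$cx[j])
        rough <- rnorm(length(pix))
        f <- rough_frac[i]
        g <- (1 - f) * .unit_field(smooth) + f * .unit_field(rough)
        g <- .unit_field(g)
        tex <- 1 + cfg$texture_sd * g
        # observed spectrum a_i * r_i(l) * texture + b_i (noise added below)
        block <- (scatter[i] * tex) %o% spectra_true[i, ] + offset[i]
        # write the seed's pixel block into the cube
        idx <- rep(pix, cfg$n_bands) +
          rep((seq_len(cfg$n_bands) - 1) * px * px, each = length(pix))
        S[idx] <- block
      }
      if (cfg$noise_sd > 0) {
        S <- S + array(rnorm(length(S), sd = cfg$noise_sd), dim(S))
      }
      # raw capture: O = Y + S * (X - Y) so Eq-style calibration inverts it
      X <- array(cfg$white_level, dim(S))
      Y <- array(cfg$dark_level, dim(S))
      O <- Y + S * (X - Y)
      plates[[p]] <- raw_capture(O, X, Y, wavelengths = wl)
      masks[[p]] <- mask
      rows_tbl[[p]] <- tibble(seed_id = seed_idx, plate = p,
                              row = layout$row, col = layout$col,
                              vitality_cm = vitality[seed_idx])
    }

    ds <- list(plates = plates,
               wavelengths = wl,
               masks = masks,
               vitality = bind_rows(rows_tbl),
               truth = list(spectra_true = spectra_true,
                            informative_band_indices = .informative_bands(wl, ab),
                            texture_latent = t_lat,
                            spectral_latent = v_spec,
                            scatter = scatter,
                            offset = offset),
               config = cfg)
    class(ds) <- "vs_dataset"
    ds
  })
}

#' @export
print.vs_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<vs_dataset> %d plates x %d seeds, %d bands (%.1f-%.1f nm), plate %dpx\n",
    cfg$n_plates, cfg$seeds_per_plate, cfg$n_bands,
    min(x$wavelengths), max(x$wavelengths), cfg$plate_px))
  invisible(x)
}

#' Write a simulated dataset to disk as analysis-ready files
#'
#' Writes one calibrated ENVI raw/header pair per plate, one 8-bit label
#' mask PNG per plate, and a vitality CSV, then returns a manifest listing
#' every file with its MD5 checksum.
#'
#' @param dataset a `vs_dataset` from [simulate_dataset()].
#' @param out_dir output directory (created if missing).
#' @param interleave ENVI interleave for the cubes.
#' @return A tibble manifest with columns `file` and `md5`.
#' @export
write_fixture <- function(dataset, out_dir, interleave = "bil") {
  stopifnot(inherits(dataset, "vs_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  files <- character(0)
  for (p in seq_along(dataset$plates)) {
    cube <- correct_reflectance(dataset$plates[[p]])
    base <- file.path(out_dir, sprintf("plate%02d", p))
    files <- c(files, write_envi(cube$S, cube$wavelengths, base,
                                 interleave = interleave))
    mp <- file.path(out_dir, sprintf("mask%02d.png", p))
    write_mask(dataset$masks[[p]], mp)
    files <- c(files, mp)
  }
  vp <- file.path(out_dir, "vitality.csv")
  write.csv(dataset$vitality, vp, row.names = FALSE)
  files <- c(files, vp)
  tibble(file = basename(files),
         md5 = unname(tools::md5sum(files)))
}
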