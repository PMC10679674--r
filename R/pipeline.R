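# End-to-end orchestration: simulate -> calibrate -> extract -> preprocess
# -> select -> texture -> fuse -> split -> fit -> evaluate, over a grid of
# (pretreatment x selector x model x feature mode) cells sharing one SPXY
# partition.

#' Concatenate selected-wavelength spectra with their texture features
#'
#' Fuses, per seed, the spectral values at the selected wavelengths with
#' the four GLCM texture features of the images at those same wavelengths:
#' `[spectral block | texture block]`, band-major. With m selected
#' wavelengths the fused width is `m + 4m = 5m`.
#'
#' @param spectral_matrix seeds x m matrix of selected-wavelength
#'   reflectance.
#' @param texture_matrix seeds x 4m matrix from [seed_texture_matrix()]
#'   over the same wavelengths.
#' @return Fused seeds x 5m matrix.
#' @export
fuse_features <- function(spectral_matrix, texture_matrix) {
  spectral_matrix <- as.matrix(spectral_matrix)
  texture_matrix <- as.matrix(texture_matrix)
  if (ncol(texture_matrix) == 0) stopf("texture block is empty; nothing to fuse")
  if (nrow(spectral_matrix) != nrow(texture_matrix)) {
    stopf("seed counts differ: %d spectral vs %d texture rows",
          nrow(spectral_matrix), nrow(texture_matrix))
  }
  if (ncol(texture_matrix) != 4 * ncol(spectral_matrix)) {
    stopf("band-set mismatch: texture has %d columns, expected 4 x %d = %d",
          ncol(texture_matrix), ncol(spectral_matrix), 4 * ncol(spectral_matrix))
  }
  cbind(spectral_matrix, texture_matrix)
}

# standardize columns of a train/test pair with the training statistics
.autoscale_pair <- function(F_tr, F_te) {
  ctr <- colMeans(F_tr)
  scl <- apply(F_tr, 2, sd)
  scl[scl == 0] <- 1
  list(tr = sweep(sweep(F_tr, 2, ctr), 2, scl, "/"),
       te = sweep(sweep(F_te, 2, ctr), 2, scl, "/"))
}

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic dataset (ignored
#'   when `dataset` is supplied to [run_pipeline()]).
#' @param preprocess pretreatments to grid over: subset of
#'   `c("SG", "SNV", "MSC")`.
#' @param selectors wavelength selectors: subset of `c("SPA", "CARS")`.
#' @param models regressors: subset of `c("PLSR", "SVR", "CNN")`.
#' @param modes feature modes: subset of
#'   `c("spectral", "texture", "fused")`.
#' @param train_fraction SPXY training fraction (default 0.7).
#' @param spa_max_vars largest SPA subset size.
#' @param cars_n_mc,cars_cv_folds CARS Monte-Carlo iterations and CV folds.
#' @param plsr_components PLSR (and CARS-internal PLS) latent variables.
#' @param svr_params list of [fit_svr()] arguments.
#' @param cnn list of [cnn_spec()] arguments.
#' @param glcm_levels,glcm_distance,glcm_angle GLCM parameters for the
#'   texture stage.
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir optional directory: report written as CSV and JSON.
#' @param quiet suppress stage messages.
#' @return A `vs_run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       preprocess = c("SG", "SNV", "MSC"),
                       selectors = c("SPA", "CARS"),
                       models = c("PLSR", "SVR", "CNN"),
                       modes = c("spectral", "texture", "fused"),
                       train_fraction = 0.7,
                       spa_max_vars = 30,
                       cars_n_mc = 100, cars_cv_folds = 5,
                       plsr_components = 3,
                       svr_params = list(),
                       cnn = list(),
                       glcm_levels = 16, glcm_distance = 1, glcm_angle = 0,
                       seed = 42, out_dir = NULL, quiet = FALSE) {
  preprocess <- match.arg(preprocess, several.ok = TRUE)
  selectors <- match.arg(selectors, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(sim = sim, preprocess = preprocess, selectors = selectors,
                 models = models, modes = modes,
                 train_fraction = train_fraction,
                 spa_max_vars = spa_max_vars,
                 cars_n_mc = cars_n_mc, cars_cv_folds = cars_cv_folds,
                 plsr_components = plsr_components,
                 svr_params = svr_params, cnn = cnn,
                 glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 glcm_angle = glcm_angle,
                 seed = seed, out_dir = out_dir, quiet = quiet),
            class = "vs_run_config")
}

#' Run the full analysis grid
#'
#' Simulates (or accepts) a plate dataset, calibrates it, extracts per-seed
#' spectra, computes one shared SPXY split, then for every grid cell fits
#' and evaluates a vitality model. Wavelength selection is done once per
#' (pretreatment, selector) pair on training data only and reused across
#' models and feature modes; texture matrices are computed per unique
#' selected band set from segmentation masks (Otsu + connected components,
#' scored against the ground-truth masks with PA/MIoU).
#'
#' @param config a [run_config()].
#' @param dataset optional pre-built `vs_dataset` (overrides `config$sim`).
#' @param split optional pre-computed `vs_split` (shared SPXY split).
#' @return A `vs_report`: tibble with one row per grid cell (`model`,
#'   `preprocessing`, `mode`, `VN`, `R_C`, `RMSE_C`, `R_P`, `RMSE_P`) and
#'   attributes `segmentation` (per-plate PA/MIoU tibble), `selections`,
#'   `split`, and `loss_curves` (CNN cells).
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL, split = NULL) {
  stopifnot(inherits(config, "vs_run_config"))
  say <- function(fmt, ...) if (!config$quiet)
    inform(sprintf(paste0("[vitaspec] ", fmt), ...))
  t0 <- Sys.time()

  if (is.null(dataset)) {
    say("simulating dataset (%d plates x %d seeds, %d bands)",
        config$sim$n_plates, config$sim$seeds_per_plate, config$sim$n_bands)
    dataset <- simulate_dataset(config$sim)
  }
  ds <- dataset_spectra(dataset)
  X_raw <- ds$spectra
  y <- ds$vitality$vitality_cm
  n_bands <- ncol(X_raw)

  # shared SPXY partition on raw spectra, before any pretreatment
  split <- split %||% spxy_split(X_raw, y, config$train_fraction)
  tr <- split$train_ids; te <- split$test_ids
  say("SPXY split: %d train / %d test", length(tr), length(te))

  # segmentation: one mask per plate from the mean-over-bands image,
  # scored against ground truth
  cubes <- calibrate_plates(dataset)
  seg_masks <- vector("list", length(cubes))
  seg_rows <- vector("list", length(cubes))
  for (p in seq_along(cubes)) {
    mean_img <- apply(cubes[[p]]$S, c(1, 2), mean)
    sm <- segment_plate(mean_img)
    seg_rows[[p]] <- tibble(plate = p,
                            n_segments = max(sm),
                            pa = pixel_accuracy(sm, dataset$masks[[p]]),
                            miou = mean_iou(sm, dataset$masks[[p]]))
    if (max(sm) != dataset$config$seeds_per_plate) {
      # seed-to-row correspondence would break; use the reference mask for
      # texture and keep the segmentation score as measured
      warnf("plate %d: segmentation found %d regions (expected %d); using reference mask for texture",
            p, max(sm), dataset$config$seeds_per_plate)
      sm <- dataset$masks[[p]]
    }
    seg_masks[[p]] <- sm
  }
  segmentation <- bind_rows(seg_rows)
  say("segmentation: mean PA %.2f%%, mean MIoU %.2f%%",
      mean(segmentation$pa), mean(segmentation$miou))

  texture_cache <- new.env(parent = emptyenv())
  texture_for <- function(band_idx) {
    key <- paste(band_idx, collapse = ",")
    if (!is.null(texture_cache[[key]])) return(texture_cache[[key]])
    mats <- mapply(function(cu, m)
      seed_texture_matrix(cu, m, band_idx, levels = config$glcm_levels,
                          distance = config$glcm_distance,
                          angle = config$glcm_angle,
                          wavelengths = dataset$wavelengths),
      cubes, seg_masks, SIMPLIFY = FALSE)
    tm <- do.call(rbind, mats)
    texture_cache[[key]] <- tm
    tm
  }

  selections <- list()
  rows <- list()
  loss_curves <- list()

  for (pp in config$preprocess) {
    fit_pp <- preprocess_fit(X_raw[tr, , drop = FALSE], method = pp)
    X_tr <- preprocess_apply(fit_pp, X_raw[tr, , drop = FALSE])
    X_te <- preprocess_apply(fit_pp, X_raw[te, , drop = FALSE])

    for (sel in config$selectors) {
      sel_key <- paste(pp, sel, sep = " + ")
      say("selecting wavelengths: %s", sel_key)
      if (sel == "SPA") {
        sub <- spxy_split(X_tr, y[tr], train_fraction = 0.8)
        selection <- spa_select(X_tr[sub$train_ids, , drop = FALSE],
                                y[tr][sub$train_ids],
                                X_tr[sub$test_ids, , drop = FALSE],
                                y[tr][sub$test_ids],
                                max_vars = config$spa_max_vars)
      } else {
        selection <- cars_select(X_tr, y[tr], n_mc = config$cars_n_mc,
                                 cv_folds = config$cars_cv_folds,
                                 n_pls_components = config$plsr_components,
                                 rng_seed = derive_seed(config$seed, sel_key))
      }
      selections[[sel_key]] <- selection
      idx <- selection$indices
      say("%s: %d wavelengths selected", sel_key, length(idx))

      spec_tr <- X_tr[, idx, drop = FALSE]
      spec_te <- X_te[, idx, drop = FALSE]
      tex_all <- if (any(c("texture", "fused") %in% config$modes))
        texture_for(idx)

      for (mode in config$modes) {
        F_tr <- switch(mode,
                       spectral = spec_tr,
                       texture = tex_all[tr, , drop = FALSE],
                       fused = fuse_features(spec_tr, tex_all[tr, , drop = FALSE]))
        F_te <- switch(mode,
                       spectral = spec_te,
                       texture = tex_all[te, , drop = FALSE],
                       fused = fuse_features(spec_te, tex_all[te, , drop = FALSE]))
        # autoscale with training statistics: reflectance and the four GLCM
        # features live on very different scales, and fused blocks must not
        # compete by variance alone
        sc <- .autoscale_pair(F_tr, F_te)
        F_tr <- sc$tr; F_te <- sc$te
        for (mod in config$models) {
          cell <- sprintf("%s | %s | %s", mod, sel_key, mode)
          res <- tryCatch({
            cnn_args <- utils::modifyList(
              list(rng_seed = derive_seed(config$seed, cell)), config$cnn)
            model <- fit_model(mod, F_tr, y[tr],
                               plsr_components = config$plsr_components,
                               svr_params = config$svr_params,
                               cnn_spec = do.call(cnn_spec, cnn_args))
            m_tr <- evaluate(model, F_tr, y[tr])
            m_te <- evaluate(model, F_te, y[te])
            if (inherits(model, "vs_cnn")) {
              loss_curves[[cell]] <- model$loss_curve
            }
            tibble(model = mod, preprocessing = sel_key, mode = mode,
                   VN = ncol(F_tr),
                   R_C = m_tr$r, RMSE_C = m_tr$rmse,
                   R_P = m_te$r, RMSE_P = m_te$rmse)
          }, error = function(e) {
            warnf("cell '%s' failed: %s", cell, conditionMessage(e))
            NULL
          })
          if (!is.null(res)) rows[[cell]] <- res
        }
      }
    }
  }

  report <- bind_rows(rows)
  class(report) <- c("vs_report", class(report))
  attr(report, "segmentation") <- segmentation
  attr(report, "selections") <- selections
  attr(report, "split") <- split
  attr(report, "loss_curves") <- loss_curves
  say("done: %d report rows in %.1f s", nrow(report),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report a `vs_report` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written (`report.csv`, `report.json`,
#'   `segmentation.csv`).
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv <- file.path(out_dir, "report.csv")
  write.csv(as.data.frame(report), csv, row.names = FALSE)
  js <- file.path(out_dir, "report.json")
  jsonlite::write_json(as.data.frame(report), js, digits = NA, pretty = TRUE)
  seg <- file.path(out_dir, "segmentation.csv")
  write.csv(as.data.frame(attr(report, "segmentation")), seg, row.names = FALSE)
  invisible(c(csv, js, seg))
}
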