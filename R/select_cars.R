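# Competitive adaptive reweighted sampling (CARS) wavelength selection.

#' Wavelength selection by competitive adaptive reweighted sampling
#'
#' At each of `n_mc` Monte-Carlo iterations a PLS model is fitted on a row
#' subsample of the currently retained wavelengths; wavelengths compete via
#' their normalised absolute regression coefficients. An exponentially
#' decreasing function (EDF) forces the retained fraction from 1 at the
#' first iteration down to `2/p` at the last (its constants are uniquely
#' determined by those endpoints); within that budget the strongest
#' wavelengths are kept and then re-drawn by adaptive reweighted sampling
#' (weighted draw with replacement, duplicates collapsed). Each retained
#' set is scored by k-fold cross-validated RMSE (RMSECV), and the set with
#' minimal RMSECV is returned: the initial fall of RMSECV marks the removal
#' of uninformative wavelengths, the late rise the loss of informative
#' ones.
#'
#' @param X spectra matrix (training rows only).
#' @param y response vector.
#' @param n_mc number of Monte-Carlo iterations (default 100).
#' @param cv_folds folds for RMSECV (default 5).
#' @param n_pls_components PLS components used throughout (default 3).
#' @param mc_fraction fraction of rows drawn (without replacement) for each
#'   Monte-Carlo fit.
#' @param rng_seed integer seed; the run is bit-reproducible given it.
#' @return A `vs_selection` with `method = "CARS"`, sorted `indices` (the
#'   set at minimal RMSECV), `rmsecv_path`, `retained_path` (number of
#'   wavelengths entering each iteration; starts at `p`, non-increasing),
#'   `coef_paths` (iterations x p coefficient matrix, 0 where dropped),
#'   `chosen_iteration`, and `sets` (the retained set after each
#'   iteration).
#' @export
cars_select <- function(X, y, n_mc = 100, cv_folds = 5,
                        n_pls_components = 3, mc_fraction = 0.8,
                        rng_seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < cv_folds) stopf("need at least as many rows (%d) as CV folds (%d)", n, cv_folds)
  if (n_pls_components >= n) stopf("n_pls_components must be below the row count")

  # EDF r_i = a * exp(-k * i) with r_1 = 1 and r_{n_mc} = 2/p
  k_edf <- log(p / 2) / (n_mc - 1)
  a_edf <- exp(k_edf)
  ratio <- a_edf * exp(-k_edf * seq_len(n_mc))

  with_seed(rng_seed, {
    retained <- seq_len(p)
    retained_path <- integer(0)
    rmsecv_path <- numeric(0)
    sets <- list()
    coef_paths <- matrix(0, n_mc, p)

    for (i in seq_len(n_mc)) {
      retained_path[i] <- length(retained)
      n_sub <- max(2, round(mc_fraction * n))
      rows <- sample.int(n, n_sub)
      a_i <- min(n_pls_components, length(retained), n_sub - 1)
      fit <- fit_plsr(X[rows, retained, drop = FALSE], y[rows], components = a_i)
      w <- abs(fit$coefficients)
      coef_paths[i, retained] <- fit$coefficients
      if (sum(w) == 0) w <- rep(1, length(w))
      w <- w / sum(w)

      keep_n <- min(length(retained), max(n_pls_components, round(ratio[i] * p)))
      ord <- order(-w, retained)  # ties: lowest band index wins
      kept <- retained[ord[seq_len(keep_n)]]
      w_kept <- w[ord[seq_len(keep_n)]]
      # adaptive reweighted sampling among the kept wavelengths: p weighted
      # draws with replacement, duplicates collapsed
      draw <- sample(kept, size = p, replace = TRUE,
                     prob = if (sum(w_kept) > 0) w_kept else NULL)
      new_set <- sort(unique(draw))
      if (length(new_set) < n_pls_components) {
        inform(sprintf(
          "CARS: stopped at iteration %d (retained %d < %d PLS components); paths truncated",
          i, length(new_set), n_pls_components))
        coef_paths <- coef_paths[seq_len(i), , drop = FALSE]
        retained <- new_set
        sets[[i]] <- retained
        rmsecv_path[i] <- NA_real_
        break
      }
      retained <- new_set
      sets[[i]] <- retained
      rmsecv_path[i] <- pls_rmsecv(X[, retained, drop = FALSE], y,
                                   components = min(n_pls_components,
                                                    length(retained)),
                                   folds = cv_folds)
    }

    chosen <- which.min(rmsecv_path)  # ties: earliest iteration
    structure(list(method = "CARS",
                   indices = sets[[chosen]],
                   rmsecv_path = rmsecv_path,
                   retained_path = retained_path,
                   coef_paths = coef_paths,
                   chosen_iteration = chosen,
                   sets = sets,
                   n_bands = p,
                   n_mc = n_mc, cv_folds = cv_folds,
                   n_pls_components = n_pls_components,
                   rng_seed = rng_seed),
              class = "vs_selection")
  })
}

#' Did a selection recover the planted absorption features?
#'
#' A planted Gaussian absorption feature spans several collinear adjacent
#' bands; a feature counts as recovered when the selected set intersects
#' its planted (FWHM) band window.
#'
#' @param selection a `vs_selection`.
#' @param informative_band_indices list of integer vectors, one per planted
#'   feature (as in `dataset$truth$informative_band_indices`).
#' @return Logical vector, one entry per planted feature.
#' @export
bands_recovered <- function(selection, informative_band_indices) {
  vapply(informative_band_indices,
         function(idx) any(selection$indices %in% idx), logical(1))
}
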