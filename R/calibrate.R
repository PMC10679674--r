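# Reflectance calibration and per-seed extraction.

#' Construct a raw capture (raw cube plus reference frames)
#'
#' @param O raw digital-number cube `(lines, samples, bands)`.
#' @param X white-reference cube, same shape as `O`.
#' @param Y dark-current cube, same shape as `O`.
#' @param wavelengths band centres in nm, strictly increasing.
#' @param average_references if `TRUE`, `X` and `Y` are replaced by their
#'   mean over lines (repeated back to full shape) before calibration; this
#'   suppresses reference-frame noise when plate-sized references were
#'   captured.
#' @return A `vs_raw_capture` list.
#' @export
raw_capture <- function(O, X, Y, wavelengths, average_references = FALSE) {
  dO <- dim(O)
  if (length(dO) != 3) stopf("O must be a 3-d array")
  if (!identical(dO, dim(X)) || !identical(dO, dim(Y))) {
    stopf("O, X, Y must share one shape; got O %s, X %s, Y %s",
          paste(dO, collapse = "x"), paste(dim(X), collapse = "x"),
          paste(dim(Y), collapse = "x"))
  }
  if (length(wavelengths) != dO[3]) {
    stopf("wavelengths length %d != bands %d", length(wavelengths), dO[3])
  }
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing")
  if (average_references) {
    X <- .average_over_lines(X)
    Y <- .average_over_lines(Y)
  }
  structure(list(O = O, X = X, Y = Y, wavelengths = wavelengths),
            class = "vs_raw_capture")
}

.average_over_lines <- function(A) {
  m <- apply(A, c(2, 3), mean)  # samples x bands
  array(rep(m, each = dim(A)[1]), dim(A))
}

#' Black/white reflectance calibration
#'
#' Converts raw digital numbers to reflectance with the standard two-point
#' correction `S = (O - Y) / (X - Y)`, where `O` is the raw cube, `X` the
#' white-reference and `Y` the dark-current frame. Locations where
#' `X == Y` (no usable dynamic range) are set to 0 and counted in a
#' warning; if the denominator is degenerate everywhere this is an error.
#'
#' @param raw a [raw_capture()].
#' @return A `vs_cube`: list with `S` (reflectance array) and `wavelengths`.
#' @export
correct_reflectance <- function(raw) {
  stopifnot(inherits(raw, "vs_raw_capture"))
  denom <- raw$X - raw$Y
  bad <- denom == 0
  n_bad <- sum(bad)
  if (n_bad == length(denom)) {
    stopf("calibration impossible: white and dark frames are identical everywhere")
  }
  S <- (raw$O - raw$Y) / denom
  if (n_bad > 0) {
    S[bad] <- 0
    warnf("%d location(s) had white == dark; reflectance set to 0 there", n_bad)
  }
  structure(list(S = S, wavelengths = raw$wavelengths), class = "vs_cube")
}

#' @export
print.vs_cube <- function(x, ...) {
  d <- dim(x$S)
  cat(sprintf("<vs_cube> %d lines x %d samples x %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Extract per-seed mean spectra from a calibrated cube
#'
#' Each seed (mask label) becomes one spectrum: the per-band summary of the
#' reflectance over its mask pixels. Each seed thus corresponds to a single
#' row of spectral data.
#'
#' @param cube a `vs_cube` from [correct_reflectance()], or a bare 3-d array.
#' @param mask integer label matrix (0 background, 1..K seeds) matching the
#'   cube's spatial shape.
#' @param summary `"mean"` (default) or `"median"` pixel summary.
#' @return Matrix `(K, bands)`; row k is the spectrum of label k.
#' @export
extract_seed_spectra <- function(cube, mask, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  S <- if (inherits(cube, "vs_cube")) cube$S else cube
  d <- dim(S)
  if (!identical(d[1:2], dim(mask))) {
    stopf("mask shape %s does not match cube spatial shape %s",
          paste(dim(mask), collapse = "x"), paste(d[1:2], collapse = "x"))
  }
  labels <- seq_len(max(mask))
  out <- matrix(NA_real_, length(labels), d[3])
  flat <- matrix(S, d[1] * d[2], d[3])  # pixels x bands
  for (k in labels) {
    pix <- which(mask == k)
    if (length(pix) == 0) stopf("mask label %d has no pixels", k)
    out[k, ] <- if (summary == "mean") colMeans(flat[pix, , drop = FALSE])
                else apply(flat[pix, , drop = FALSE], 2, median)
  }
  out
}

#' Extract the image at a single wavelength point
#'
#' @param cube a `vs_cube` or bare 3-d array.
#' @param band_index 1-based band index.
#' @return The spatial matrix at that band, untransformed.
#' @export
extract_band_image <- function(cube, band_index) {
  S <- if (inherits(cube, "vs_cube")) cube$S else cube
  nb <- dim(S)[3]
  if (!is_count(band_index) || band_index > nb) {
    stopf("band index %s out of range [1, %d]", format(band_index), nb)
  }
  S[, , band_index]
}

# calibrate every plate of a dataset; returns list of vs_cube
calibrate_plates <- function(dataset) {
  lapply(dataset$plates, correct_reflectance)
}

#' Per-seed spectra and vitality table for a whole dataset
#'
#' Calibrates every plate, extracts per-seed mean spectra with the
#' ground-truth masks (the manual-ROI analogue), and joins the vitality
#' table.
#'
#' @param dataset a `vs_dataset`.
#' @param summary pixel summary passed to [extract_seed_spectra()].
#' @return List with `spectra` (seeds x bands matrix, rows ordered by
#'   seed_id), `vitality` (tibble) and `wavelengths`.
#' @export
dataset_spectra <- function(dataset, summary = "mean") {
  cubes <- calibrate_plates(dataset)
  mats <- mapply(function(cu, m) extract_seed_spectra(cu, m, summary = summary),
                 cubes, dataset$masks, SIMPLIFY = FALSE)
  spectra <- do.call(rbind, mats)
  rownames(spectra) <- dataset$vitality$seed_id
  list(spectra = spectra, vitality = dataset$vitality,
       wavelengths = dataset$wavelengths)
}
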