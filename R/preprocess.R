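# Spectral pretreatments: SNV, MSC, Savitzky-Golay smoothing.

#' Standard normal variate transform
#'
#' Centres and scales each spectrum (row) to mean 0 and unit sample
#' standard deviation, correcting scatter-induced offset and slope.
#'
#' @param spectra numeric matrix, one spectrum per row.
#' @return Matrix of the same shape; each row has mean 0 and sd 1.
#' @export
snv <- function(spectra) {
  X <- as_matrix_rows(spectra)
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  if (any(s == 0)) {
    stopf("SNV undefined for constant spectrum in row(s) %s",
          paste(which(s == 0), collapse = ", "))
  }
  (X - mu) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a * ref + b`, and
#' inverts the fitted affine model: the corrected spectrum is
#' `(x - b) / a`. With the reference equal to the mean training spectrum
#' this removes per-sample multiplicative and additive scatter.
#'
#' @param spectra numeric matrix, one spectrum per row.
#' @param reference reference spectrum; defaults to the column mean of
#'   `spectra`. When preprocessing a test set, pass the training-set mean.
#' @return Corrected matrix, same shape as `spectra`.
#' @export
msc <- function(spectra, reference = NULL) {
  X <- as_matrix_rows(spectra)
  ref <- reference %||% colMeans(X)
  if (length(ref) != ncol(X)) {
    stopf("reference length %d != %d bands", length(ref), ncol(X))
  }
  if (sd(ref) == 0) stopf("MSC reference has zero spread")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    a <- sum((X[i, ] - mean(X[i, ])) * rc) / denom
    if (a == 0) stopf("MSC slope is zero for row %d; correction undefined", i)
    b <- mean(X[i, ]) - a * mean(ref)
    out[i, ] <- (X[i, ] - b) / a
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by its moving local polynomial least-squares fit
#' (no derivative). Edges are handled by evaluating the polynomial fitted
#' to the terminal windows, so polynomials up to the fit order are
#' reproduced exactly everywhere.
#'
#' @param spectra numeric matrix, one spectrum per row.
#' @param window odd window length, `window > polyorder` and
#'   `window <= bands`.
#' @param polyorder polynomial order of the local fit.
#' @return Smoothed matrix, same shape.
#' @export
sg_smooth <- function(spectra, window = 11, polyorder = 2) {
  X <- as_matrix_rows(spectra)
  if (window %% 2 == 0 || window <= polyorder) {
    stopf("SG window must be odd and greater than the polynomial order (got window %d, order %d)",
          window, polyorder)
  }
  if (window > ncol(X)) {
    stopf("SG window %d exceeds the number of bands (%d)", window, ncol(X))
  }
  t(apply(X, 1, function(row) signal::sgolayfilt(row, p = polyorder, n = window)))
}

#' Fit a pretreatment on training spectra
#'
#' Freezes everything the transform needs (for MSC, the training-mean
#' reference) so the identical transform can be applied to test spectra
#' without information leaking from the test fold.
#'
#' @param X_train training spectra matrix.
#' @param method `"SG"`, `"SNV"`, `"MSC"`, or `"none"`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param msc_reference explicit MSC reference spectrum, or `NULL` for the
#'   training-set mean.
#' @return A `vs_preprocess` object; apply it with [preprocess_apply()].
#' @export
preprocess_fit <- function(X_train, method = c("SG", "SNV", "MSC", "none"),
                           sg_window = 11, sg_polyorder = 2,
                           msc_reference = NULL) {
  method <- match.arg(method)
  fit <- list(method = method, sg_window = sg_window,
              sg_polyorder = sg_polyorder,
              reference = if (method == "MSC")
                msc_reference %||% colMeans(as_matrix_rows(X_train)))
  class(fit) <- "vs_preprocess"
  fit
}

#' Apply a fitted pretreatment to spectra
#' @param fit a `vs_preprocess` from [preprocess_fit()].
#' @param X spectra matrix.
#' @return Transformed matrix.
#' @export
preprocess_apply <- function(fit, X) {
  stopifnot(inherits(fit, "vs_preprocess"))
  switch(fit$method,
         SG = sg_smooth(X, fit$sg_window, fit$sg_polyorder),
         SNV = snv(X),
         MSC = msc(X, fit$reference),
         none = as_matrix_rows(X))
}
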