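# Gray-level co-occurrence matrices and the four texture features
# (contrast, correlation, energy, entropy) used per seed per wavelength.

# pixel offset (d_row, d_col) for a GLCM angle in degrees and a distance
.glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
         "0" = c(0L, distance),
         "45" = c(-distance, distance),
         "90" = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stopf("GLCM angle must be one of 0, 45, 90, 135 degrees"))
}

# quantize values to 1..levels with equal-width bins over their range;
# a constant patch maps to level 1
.glcm_quantize <- function(x, levels) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  q <- floor((x - rng[1]) / diff(rng) * levels) + 1L
  pmin(q, levels)
}

# index pairs (i, j) of valid co-occurring pixels in a patch, honouring an
# optional validity mask: pairs touching an invalid pixel are dropped
.glcm_pairs <- function(dim_patch, offset, valid = NULL) {
  nr <- dim_patch[1]; nc <- dim_patch[2]
  dr <- offset[1]; dc <- offset[2]
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  r_ok <- r0[r0 + dr >= 1 & r0 + dr <= nr]
  c_ok <- c0[c0 + dc >= 1 & c0 + dc <= nc]
  if (length(r_ok) == 0 || length(c_ok) == 0) {
    return(list(from = integer(0), to = integer(0)))
  }
  from_r <- rep(r_ok, times = length(c_ok))
  from_c <- rep(c_ok, each = length(r_ok))
  from <- (from_c - 1L) * nr + from_r
  to <- (from_c + dc - 1L) * nr + (from_r + dr)
  if (!is.null(valid)) {
    ok <- valid[from] & valid[to]
    from <- from[ok]; to <- to[ok]
  }
  list(from = from, to = to)
}

#' Gray-level co-occurrence matrix of an image patch
#'
#' Counts co-occurring gray-level pairs at a fixed pixel offset, optionally
#' symmetrized (counts plus their transpose), and normalizes the counts to
#' sum to one.
#'
#' @param patch numeric matrix; quantized internally to `levels` equal-width
#'   gray bins spanning the patch range.
#' @param levels number of gray levels (default 16).
#' @param distance pixel offset distance (default 1).
#' @param angle offset direction in degrees: 0, 45, 90 or 135.
#' @param symmetric if `TRUE` (default) the matrix is symmetrized.
#' @param mask optional logical matrix marking valid pixels; pairs touching
#'   an invalid pixel are excluded.
#' @return `levels x levels` matrix `p` with `sum(p) == 1`.
#' @export
glcm <- function(patch, levels = 16, distance = 1, angle = 0,
                 symmetric = TRUE, mask = NULL) {
  patch <- as.matrix(patch)
  off <- .glcm_offset(angle, as.integer(distance))
  valid <- if (!is.null(mask)) as.vector(mask) else NULL
  pr <- .glcm_pairs(dim(patch), off, valid)
  if (length(pr$from) == 0) {
    stopf("GLCM has no valid pixel pairs (patch too small for offset)")
  }
  vals <- if (!is.null(valid)) {
    x <- as.vector(patch)
    q <- rep(NA_integer_, length(x))
    q[valid] <- .glcm_quantize(x[valid], levels)
    q
  } else {
    .glcm_quantize(as.vector(patch), levels)
  }
  counts <- tabulate((vals[pr$from] - 1L) * levels + vals[pr$to],
                     nbins = levels * levels)
  G <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) G <- G + t(G)
  G / sum(G)
}

#' Texture features of a normalized GLCM
#'
#' Contrast \eqn{\sum (i-j)^2 p(i,j)}, correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}, energy
#' \eqn{\sum p(i,j)^2}, and entropy \eqn{-\sum p \log_2 p} (with
#' \eqn{0 \log 0 = 0}). If a marginal is degenerate (\eqn{\sigma = 0}),
#' correlation is reported as 0 with a warning.
#'
#' @param p normalized GLCM from [glcm()].
#' @return Named numeric vector `contrast`, `correlation`, `energy`,
#'   `entropy`.
#' @export
texture_features <- function(p) {
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  contrast <- sum((i - j)^2 * p)
  if (var_i == 0 || var_j == 0) {
    warnf("GLCM marginal has zero variance; correlation reported as 0")
    correlation <- 0
  } else {
    correlation <- sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  }
  energy <- sum(p^2)
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  c(contrast = contrast, correlation = correlation,
    energy = energy, entropy = entropy)
}

#' Per-seed GLCM texture matrix over selected wavelengths
#'
#' For each seed (mask label) and each requested band, extracts the masked
#' bounding-box patch of the band image and computes the four GLCM texture
#' features. Pairs touching background pixels are excluded from the
#' co-occurrence counts. Columns are band-major in the order contrast,
#' correlation, energy, entropy, named `<band_nm>_<feature>`.
#'
#' @param cube a `vs_cube` or bare `(lines, samples, bands)` array.
#' @param mask integer label matrix (1..K seeds).
#' @param band_indices 1-based band indices to extract texture at.
#' @param levels,distance,angle,symmetric GLCM parameters (see [glcm()]).
#' @param wavelengths optional nm axis used for column names; taken from
#'   the cube when available.
#' @return Matrix `(K, 4 * length(band_indices))`.
#' @export
seed_texture_matrix <- function(cube, mask, band_indices, levels = 16,
                                distance = 1, angle = 0, symmetric = TRUE,
                                wavelengths = NULL) {
  S <- if (inherits(cube, "vs_cube")) cube$S else cube
  wavelengths <- wavelengths %||%
    (if (inherits(cube, "vs_cube")) cube$wavelengths else seq_len(dim(S)[3]))
  nb <- dim(S)[3]
  if (any(band_indices < 1 | band_indices > nb)) {
    stopf("band indices out of range [1, %d]", nb)
  }
  K <- max(mask)
  feats <- c("contrast", "correlation", "energy", "entropy")
  out <- matrix(NA_real_, K, 4 * length(band_indices))
  colnames(out) <- as.vector(vapply(band_indices, function(b) {
    paste0(round(wavelengths[b]), "nm_", feats)
  }, character(4)))
  off <- .glcm_offset(angle, as.integer(distance))
  L2 <- levels * levels

  for (k in seq_len(K)) {
    pix <- which(mask == k, arr.ind = TRUE)
    if (nrow(pix) == 0) stopf("seed %d has no mask pixels", k)
    rr <- range(pix[, 1]); cc <- range(pix[, 2])
    if (diff(rr) < 1 || diff(cc) < 1) {
      stopf("seed %d has a degenerate (< 2x2) bounding box", k)
    }
    sub_valid <- mask[rr[1]:rr[2], cc[1]:cc[2]] == k
    pr <- .glcm_pairs(dim(sub_valid), off, as.vector(sub_valid))
    if (length(pr$from) == 0) {
      stopf("seed %d has no valid GLCM pixel pairs", k)
    }
    for (bi in seq_along(band_indices)) {
      patch <- S[rr[1]:rr[2], cc[1]:cc[2], band_indices[bi]]
      x <- as.vector(patch)
      q <- rep(NA_integer_, length(x))
      q[sub_valid] <- .glcm_quantize(x[as.vector(sub_valid)], levels)
      counts <- tabulate((q[pr$from] - 1L) * levels + q[pr$to], nbins = L2)
      G <- matrix(counts, levels, levels, byrow = TRUE)
      if (symmetric) G <- G + t(G)
      p <- G / sum(G)
      out[k, (bi - 1) * 4 + 1:4] <- texture_features(p)
    }
  }
  out
}
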