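# shared fixtures, all generated in code

.vs_cache <- new.env()

# the full default synthetic dataset (study conditions), built once per run
default_dataset <- function() {
  if (is.null(.vs_cache$ds)) {
    .vs_cache$ds <- simulate_dataset(sim_config(rng_seed = 42))
  }
  .vs_cache$ds
}

default_spectra <- function() {
  if (is.null(.vs_cache$dsp)) {
    .vs_cache$dsp <- dataset_spectra(default_dataset())
  }
  .vs_cache$dsp
}

# absorption features that fit inside a short (120-band, 391-540 nm) axis,
# for fast tests that still need a planted, recoverable signal
small_absorption_bands <- function() {
  data.frame(center_nm = c(420, 470, 520),
             width_nm = c(7, 7, 7),
             base = c(0.06, 0.07, 0.05),
             slope_per_cm = c(0.013, 0.012, 0.013))
}

small_planted_config <- function(...) {
  args <- utils::modifyList(
    list(n_plates = 2, n_bands = 120, plate_px = 48,
         absorption_bands = small_absorption_bands()),
    list(...))
  do.call(sim_config, args)
}

# a tiny raw capture with known reflectance, for calibration tests
toy_raw_capture <- function(S = NULL, lines = 6, samples = 5, bands = 4,
                            white = 9, dark = 1) {
  if (is.null(S)) {
    set.seed(99)
    S <- array(runif(lines * samples * bands), c(lines, samples, bands))
  }
  d <- dim(S)
  X <- array(white, d); Y <- array(dark, d)
  raw_capture(Y + S * (X - Y), X, Y, wavelengths = seq(400, by = 10,
                                                       length.out = d[3]))
}

# brute-force GLCM + features, written independently as a double loop
brute_glcm_features <- function(patch, levels, dr, dc, symmetric = TRUE) {
  q <- matrix(vitaspec:::.glcm_quantize(as.vector(patch), levels),
              nrow(patch), ncol(patch))
  G <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        G[q[r, cc], q[r2, c2]] <- G[q[r, cc], q[r2, c2]] + 1
      }
    }
  }
  if (symmetric) G <- G + t(G)
  p <- G / sum(G)
  mu_i <- 0; mu_j <- 0; contrast <- 0; energy <- 0; entropy <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  s_i <- 0; s_j <- 0; corr_num <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    energy <- energy + p[i, j]^2
    if (p[i, j] > 0) entropy <- entropy - p[i, j] * log2(p[i, j])
    s_i <- s_i + (i - mu_i)^2 * p[i, j]
    s_j <- s_j + (j - mu_j)^2 * p[i, j]
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * p[i, j]
  }
  correlation <- if (s_i == 0 || s_j == 0) 0 else corr_num / sqrt(s_i * s_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    entropy = entropy)
}
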