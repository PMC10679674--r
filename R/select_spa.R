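# Successive projections algorithm (SPA) wavelength selection.

# Build one projection chain: starting from column `start`, repeatedly pick
# the column with the largest norm after projection onto the orthogonal
# complement of the columns already chosen. Columns whose projected norm
# collapses (exact collinearity with the chain) are never selected.
.spa_chain <- function(X, start, max_vars, tol = 1e-10) {
  V <- X
  p <- ncol(X)
  chain <- integer(0)
  pick <- start
  scale0 <- max(colSums(X^2))
  for (step in seq_len(max_vars)) {
    chain <- c(chain, pick)
    u <- V[, pick]
    uu <- sum(u^2)
    if (uu <= tol * scale0) break
    V <- V - u %*% (crossprod(u, V) / uu)
    norms <- colSums(V^2)
    norms[chain] <- -Inf
    norms[norms <= tol * scale0] <- -Inf
    if (all(!is.finite(norms))) break
    pick <- which.max(norms)  # ties: lowest band index wins
  }
  chain
}

# validation RMSE of multiple linear regression (with intercept) for every
# prefix of `chain`, via one QR factorisation of the full chain design
.spa_prefix_rmse <- function(X_train, y_train, X_val, y_val, chain) {
  A <- cbind(1, X_train[, chain, drop = FALSE])
  qr_A <- qr(A)
  rmse_path <- rep(NA_real_, length(chain))
  pivoted <- !identical(qr_A$pivot, seq_len(ncol(A)))
  if (!pivoted) {
    R_full <- qr.R(qr_A)
    qty_full <- qr.qty(qr_A, y_train)
    for (k in seq_along(chain)) {
      cols <- seq_len(k + 1)
      if (qr_A$rank < k + 1) break  # rank-deficient prefix; longer ones too
      beta <- backsolve(R_full[cols, cols, drop = FALSE], qty_full[cols])
      pred <- cbind(1, X_val[, chain[seq_len(k)], drop = FALSE]) %*% beta
      rmse_path[k] <- rmse(y_val, drop(pred))
    }
  } else {
    # rare: qr pivoted the design; score prefixes one by one
    for (k in seq_along(chain)) {
      Ak <- cbind(1, X_train[, chain[seq_len(k)], drop = FALSE])
      fit <- lm.fit(Ak, y_train)
      if (fit$rank < ncol(Ak)) break
      pred <- cbind(1, X_val[, chain[seq_len(k)], drop = FALSE]) %*% fit$coefficients
      rmse_path[k] <- rmse(y_val, drop(pred))
    }
  }
  rmse_path
}

#' Wavelength selection by the successive projections algorithm
#'
#' For each candidate starting wavelength, SPA grows a chain of minimally
#' collinear wavelengths by vector projection: at every step the wavelength
#' with the largest norm after projection onto the orthogonal complement of
#' those already chosen is added. Every chain prefix is scored by the RMSE
#' of a multiple linear regression on a validation split, and the
#' (start, subset size) pair where the RMSE reaches its minimum is
#' returned.
#'
#' @param X_train,y_train training spectra and response.
#' @param X_val,y_val validation spectra and response used to score subset
#'   sizes.
#' @param max_vars largest subset size considered (default 30).
#' @param starts candidate starting columns (default: all columns).
#' @return A `vs_selection` with `method = "SPA"`, sorted `indices`,
#'   `rmse_path` (validation RMSE vs subset size for the winning start),
#'   `best_size`, `best_start`, and `best_rmse`.
#' @export
spa_select <- function(X_train, y_train, X_val, y_val, max_vars = 30,
                       starts = NULL) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  p <- ncol(X_train)
  max_vars <- min(max_vars, nrow(X_train) - 1, p)
  if (max_vars < 1) stopf("max_vars must allow at least one wavelength")
  if (any(colSums(X_train^2) == 0)) {
    stopf("SPA requires no all-zero predictor column")
  }
  starts <- starts %||% seq_len(p)

  best <- list(rmse = Inf, size = Inf, start = Inf, chain = NULL, path = NULL)
  rmse_grid <- matrix(NA_real_, length(starts), max_vars,
                      dimnames = list(NULL, NULL))
  chains <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    s <- starts[si]
    chain <- .spa_chain(X_train, s, max_vars)
    path <- .spa_prefix_rmse(X_train, y_train, X_val, y_val, chain)
    chains[[si]] <- chain
    rmse_grid[si, seq_along(path)] <- path
    if (all(is.na(path))) {
      inform(sprintf("SPA: start %d skipped (rank-deficient selection)", s))
      next
    }
    k <- which.min(path)  # ties: smaller subset wins
    r <- path[k]
    better <- r < best$rmse - 1e-12 ||
      (abs(r - best$rmse) <= 1e-12 &&
         (k < best$size || (k == best$size && s < best$start)))
    if (better) {
      best <- list(rmse = r, size = k, start = s, chain = chain, path = path)
    }
  }
  if (is.null(best$chain)) stopf("SPA found no usable candidate chain")

  structure(list(method = "SPA",
                 indices = sort(best$chain[seq_len(best$size)]),
                 selection_order = best$chain[seq_len(best$size)],
                 rmse_path = best$path,
                 best_size = best$size,
                 best_start = best$start,
                 best_rmse = best$rmse,
                 starts = starts,
                 chains = chains,
                 rmse_grid = rmse_grid,
                 n_bands = p),
            class = "vs_selection")
}

#' Best SPA subset at a fixed size
#'
#' Interrogates a fitted SPA selection for the best candidate chain prefix
#' of exactly `size` wavelengths (minimum validation RMSE over all starts).
#'
#' @param selection a `vs_selection` from [spa_select()].
#' @param size subset size.
#' @return List with `indices` (sorted) and `rmse`.
#' @export
spa_best_at_size <- function(selection, size) {
  stopifnot(inherits(selection, "vs_selection"), selection$method == "SPA")
  col <- selection$rmse_grid[, size]
  if (all(is.na(col))) stopf("no start produced a usable subset of size %d", size)
  si <- which.min(col)
  list(indices = sort(selection$chains[[si]][seq_len(size)]), rmse = col[si])
}

#' @export
print.vs_selection <- function(x, ...) {
  cat(sprintf("<vs_selection> %s: %d of %d wavelengths selected\n",
              x$method, length(x$indices), x$n_bands))
  invisible(x)
}
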