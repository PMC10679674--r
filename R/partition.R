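# SPXY sample-set partitioning (joint X-Y distance).

#' SPXY train/test partitioning
#'
#' Splits samples by joint predictor-response distance coverage: with
#' Euclidean distances \eqn{d_x} on spectra and \eqn{d_y = |y_i - y_j|} on
#' the response, each normalized by its maximum, the joint distance is
#' \eqn{d = d_x / \max d_x + d_y / \max d_y}. The training set is seeded
#' with the pair at maximal joint distance and grown by repeatedly adding
#' the sample with the largest minimum distance to the current training
#' set, until `floor(train_fraction * n)` members; the rest form the test
#' set. The procedure is deterministic; ties are broken by the smallest
#' sample index.
#'
#' @param X spectra matrix (n x p).
#' @param y response vector, length n.
#' @param train_fraction fraction of samples assigned to training
#'   (default 0.7).
#' @return A `vs_split` with sorted integer `train_ids` and `test_ids`, the
#'   `selection_order`, and a tibble `folds` (`id`, `fold`).
#' @export
spxy_split <- function(X, y, train_fraction = 0.7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stopf("SPXY needs at least 3 samples")
  stopifnot(length(y) == n)
  if (sd(y) == 0) stopf("SPXY undefined: response has zero spread")
  dx <- as.matrix(stats::dist(X))
  if (max(dx) == 0) stopf("SPXY undefined: all spectra identical (max distance 0)")
  dy <- abs(outer(y, y, "-"))
  d <- dx / max(dx) + dy / max(dy)

  n_train <- floor(train_fraction * n)
  if (n_train < 2 || n_train >= n) {
    stopf("train_fraction %.2f leaves an empty fold for n = %d", train_fraction, n)
  }

  # seed: the pair at maximal joint distance (ties: smallest indices)
  flat <- which(d == max(d), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  first <- flat[order(flat[, 1], flat[, 2])[1], ]
  sel <- as.integer(first)

  min_d <- unname(pmin(d[, sel[1]], d[, sel[2]]))
  min_d[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- as.integer(which.max(min_d))  # ties: lowest index
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, d[, nxt])
    min_d[nxt] <- -Inf
  }
  train_ids <- sort(sel)
  test_ids <- setdiff(seq_len(n), train_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 selection_order = sel,
                 folds = tibble(id = seq_len(n),
                                fold = ifelse(seq_len(n) %in% train_ids,
                                              "train", "test"))),
            class = "vs_split")
}

#' @export
print.vs_split <- function(x, ...) {
  cat(sprintf("<vs_split> %d train / %d test (SPXY)\n",
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}
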