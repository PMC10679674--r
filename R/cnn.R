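# One-dimensional convolutional network for spectral regression, trained by
# SGD on the mean-square-error loss. Implemented directly with matrix
# algebra: at the input lengths this pipeline produces (a handful to a few
# hundred selected features) the network is small enough that explicit
# forward/backward passes in R are fast and bit-reproducible.

#' Architecture and training specification for the 1D-CNN
#'
#' Defaults: two convolutional layers (64 then 128 kernels of width 3,
#' ReLU, same padding), each followed by width-2 average pooling, then a
#' 256-unit fully connected ReLU layer and a single linear output; SGD with
#' learning rate 1e-4, 50 epochs, batch size 4.
#'
#' @param conv1_filters,conv2_filters kernels in the two conv layers.
#' @param kernel_size convolution width (odd).
#' @param fc_units neurons in the first fully connected layer.
#' @param lr SGD learning rate.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param rng_seed seed for weight initialisation and shuffling.
#' @return A `vs_cnn_spec` list.
#' @export
cnn_spec <- function(conv1_filters = 64, conv2_filters = 128,
                     kernel_size = 3, fc_units = 256,
                     lr = 1e-4, epochs = 50, batch = 4, rng_seed = 1) {
  stopifnot(kernel_size %% 2 == 1, conv1_filters >= 1, conv2_filters >= 1,
            fc_units >= 1, epochs >= 1, batch >= 1, lr > 0)
  structure(list(conv1_filters = conv1_filters,
                 conv2_filters = conv2_filters,
                 kernel_size = kernel_size, fc_units = fc_units,
                 lr = lr, epochs = epochs, batch = batch,
                 rng_seed = rng_seed),
            class = "vs_cnn_spec")
}

# im2col for a length-L, C-channel sequence with same (zero) padding:
# returns L x (k*C), tap-major column blocks
.im2col <- function(x, k) {
  x <- as_matrix_cols(x)
  L <- nrow(x); C <- ncol(x)
  half <- (k - 1) / 2
  pad <- matrix(0, half, C)
  xp <- rbind(pad, x, pad)
  do.call(cbind, lapply(seq_len(k), function(j) xp[j:(j + L - 1), , drop = FALSE]))
}

# reverse of .im2col: scatter-add patch gradients back onto the sequence
.col2im <- function(dP, L, C, k) {
  half <- (k - 1) / 2
  dxp <- matrix(0, L + 2 * half, C)
  for (j in seq_len(k)) {
    cols <- (j - 1) * C + seq_len(C)
    dxp[j:(j + L - 1), ] <- dxp[j:(j + L - 1), ] + dP[, cols, drop = FALSE]
  }
  dxp[(half + 1):(half + L), , drop = FALSE]
}

as_matrix_cols <- function(x) if (is.null(dim(x))) matrix(x, ncol = 1) else x

.pool_avg2 <- function(a) {
  Lp <- floor(nrow(a) / 2)
  (a[2 * seq_len(Lp) - 1, , drop = FALSE] + a[2 * seq_len(Lp), , drop = FALSE]) / 2
}

.unpool_avg2 <- function(dp, L) {
  d <- matrix(0, L, ncol(dp))
  Lp <- nrow(dp)
  d[2 * seq_len(Lp) - 1, ] <- dp / 2
  d[2 * seq_len(Lp), ] <- dp / 2
  d
}

.cnn_forward <- function(par, x, keep = FALSE) {
  k <- par$k
  P1 <- .im2col(x, k)
  Z1 <- sweep(P1 %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  Q1 <- .pool_avg2(A1)
  P2 <- .im2col(Q1, k)
  Z2 <- sweep(P2 %*% par$W2, 2, par$b2, "+")
  A2 <- pmax(Z2, 0)
  Q2 <- .pool_avg2(A2)
  f <- as.vector(Q2)
  z3 <- drop(crossprod(par$W3, f)) + par$b3
  a3 <- pmax(z3, 0)
  out <- sum(par$W4 * a3) + par$b4
  if (!keep) return(out)
  list(out = out, P1 = P1, Z1 = Z1, A1 = A1, Q1 = Q1,
       P2 = P2, Z2 = Z2, A2 = A2, Q2 = Q2, f = f, z3 = z3, a3 = a3)
}

# gradient of 0.5-free MSE term d/dout applied through the network for one
# sample; returns the parameter gradient list
.cnn_backward <- function(par, cache, dout) {
  k <- par$k
  g <- list()
  g$b4 <- dout
  g$W4 <- dout * cache$a3
  da3 <- dout * par$W4
  dz3 <- da3 * (cache$z3 > 0)
  g$b3 <- dz3
  g$W3 <- outer(cache$f, dz3)
  df <- drop(par$W3 %*% dz3)
  dQ2 <- matrix(df, nrow(cache$Q2), ncol(cache$Q2))
  dA2 <- .unpool_avg2(dQ2, nrow(cache$A2))
  dZ2 <- dA2 * (cache$Z2 > 0)
  g$b2 <- colSums(dZ2)
  g$W2 <- crossprod(cache$P2, dZ2)
  dP2 <- dZ2 %*% t(par$W2)
  dQ1 <- .col2im(dP2, nrow(cache$Q1), ncol(cache$Q1), k)
  dA1 <- .unpool_avg2(dQ1, nrow(cache$A1))
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$b1 <- colSums(dZ1)
  g$W1 <- crossprod(cache$P1, dZ1)
  g
}

#' Fit the 1D convolutional network
#'
#' Architecture conv(64) -> avgpool -> conv(128) -> avgpool -> flatten ->
#' fc(256, ReLU) -> fc(1), trained with plain SGD on the mean square error
#' \eqn{\mathrm{MSE} = \sum_i (\hat y_i - y_i)^2 / n}. Inputs are
#' standardized per column and the response is standardized internally with
#' training statistics (predictions are returned on the original scale).
#' The per-epoch training MSE (original units) is recorded as
#' `loss_curve`.
#'
#' @param X predictor matrix (n x L); `L >= 4` so the two pooling stages
#'   have a nonempty output (the receptive-field requirement).
#' @param y numeric response.
#' @param spec a [cnn_spec()].
#' @return A `vs_cnn` model supporting [predict()], [tidy()] (loss curve)
#'   and [glance()].
#' @export
fit_cnn <- function(X, y, spec = cnn_spec()) {
  stopifnot(inherits(spec, "vs_cnn_spec"))
  X <- as.matrix(X)
  n <- nrow(X); L <- ncol(X)
  if (L < 4) {
    stopf("input length %d is shorter than the network's receptive field (need >= 4)", L)
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd); x_scale[x_scale == 0] <- 1
  y_center <- mean(y); y_scale <- sd(y)
  if (y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  k <- spec$kernel_size
  C1 <- spec$conv1_filters; C2 <- spec$conv2_filters
  L1 <- floor(L / 2); L2 <- floor(L1 / 2)
  n_flat <- L2 * C2

  par <- with_seed(spec$rng_seed, {
    he <- function(nr, nc, fan) matrix(rnorm(nr * nc, sd = sqrt(2 / fan)), nr, nc)
    list(W1 = he(k, C1, k), b1 = rep(0, C1),
         W2 = he(k * C1, C2, k * C1), b2 = rep(0, C2),
         W3 = he(n_flat, spec$fc_units, n_flat), b3 = rep(0, spec$fc_units),
         W4 = rnorm(spec$fc_units, sd = sqrt(1 / spec$fc_units)), b4 = 0,
         k = k)
  })

  loss_curve <- numeric(spec$epochs)
  par <- with_seed(derive_seed(spec$rng_seed, "cnn-train"), {
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = spec$batch)) {
        idx <- ord[b0:min(b0 + spec$batch - 1, n)]
        grads <- NULL
        for (i in idx) {
          cache <- .cnn_forward(par, Xs[i, ], keep = TRUE)
          dout <- 2 * (cache$out - ys[i]) / length(idx)
          g <- .cnn_backward(par, cache, dout)
          grads <- if (is.null(grads)) g else {
            for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
            grads
          }
        }
        for (nm in names(grads)) {
          par[[nm]] <- par[[nm]] - spec$lr * grads[[nm]]
        }
      }
      preds <- vapply(seq_len(n), function(i) .cnn_forward(par, Xs[i, ]),
                      numeric(1))
      loss_curve[epoch] <- mean((preds - ys)^2) * y_scale^2
    }
    par
  })

  structure(list(par = par, spec = spec,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 loss_curve = loss_curve, VN = L),
            class = c("vs_cnn", "vs_model"))
}

#' @export
predict.vs_cnn <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  vapply(seq_len(nrow(Xs)), function(i)
    .cnn_forward(object$par, Xs[i, ]) * object$y_scale + object$y_center,
    numeric(1))
}

#' @export
print.vs_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<vs_cnn> conv(%d)-pool-conv(%d)-pool-fc(%d)-fc(1), input %d, %d epochs, final MSE %.4g\n",
    s$conv1_filters, s$conv2_filters, s$fc_units, x$VN, s$epochs,
    x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}

#' Mean square error loss
#'
#' \eqn{\mathrm{MSE} = \sum_i (\hat y_i - y_i)^2 / n}, the training loss of
#' the 1D-CNN.
#' @param yhat predictions.
#' @param y observed values.
#' @return Scalar MSE.
#' @export
mse_loss <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  mean((yhat - y)^2)
}
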