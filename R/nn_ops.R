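# Network tensor conventions and the pieces not handled by the compiled
# kernels (src/nn_kernels.cpp).
#
# Activations are channels-first (C x n) matrices whose n columns are the
# concatenated length-L time blocks of the windows in the batch; each
# convolution is one BLAS matrix product per kernel tap, accumulated in
# place by the compiled kernels with boundary corrections so zero padding
# never leaks across windows.

he_init <- function(k, cin, cout, slope = 0.01) {
  # Kaiming initialization matched to the leaky rectifier gain
  sd <- sqrt(2 / (k * cin * (1 + slope^2)))
  lapply(seq_len(k), function(t)
    matrix(stats::rnorm(cin * cout, sd = sd), cin, cout))
}

# plain-R single-window convolution used as the independent reference for
# the compiled kernels in the test suite
conv1d_reference <- function(x, W, b) {
  cin <- nrow(x); n <- ncol(x)
  k <- length(W); half <- (k - 1) / 2
  cout <- ncol(W[[1]])
  y <- matrix(rep(b, n), cout, n)
  for (c in seq_len(n)) for (t in seq_len(k)) {
    src <- c + t - 1 - half
    if (src >= 1 && src <= n)
      y[, c] <- y[, c] + t(W[[t]]) %*% x[, src]
  }
  y
}

#' Adaptive kernel size of the efficient-channel-attention block
#'
#' Nearest odd integer to `log2(C)/2 + 1/2` (ties resolved downwards); for
#' 32 channels this gives 3.
#'
#' @param C channel count.
#' @return odd integer kernel size, at least 1.
#' @export
eca_kernel_size <- function(C) {
  t <- log2(C) / 2 + 0.5
  lo <- 2 * floor((t - 1) / 2) + 1   # largest odd <= t
  hi <- lo + 2
  k <- if (t - lo <= hi - t) lo else hi
  max(1L, as.integer(k))
}

shift_mat_rows <- function(M, s) {
  # row c of the result holds M[c + s, ], zero outside (channel-axis shift)
  if (s == 0) return(M)
  C <- nrow(M)
  Y <- matrix(0, C, ncol(M))
  src <- seq_len(C) + s
  ok <- src >= 1 & src <= C
  Y[ok, ] <- M[src[ok], , drop = FALSE]
  Y
}

# Efficient channel attention: per-channel gates from globally averaged
# channel descriptors through a 1D convolution across channels.
eca_forward <- function(X, w, L) {
  avg <- nn_block_means(X, L)                  # C x Nb
  k <- length(w)
  offs <- seq_len(k) - (k + 1) / 2
  pre <- matrix(0, nrow(avg), ncol(avg))
  for (t in seq_len(k)) pre <- pre + w[t] * shift_mat_rows(avg, offs[t])
  gate <- 1 / (1 + exp(-pre))
  list(Y = nn_scale_blocks(X, gate, L), avg = avg, gate = gate)
}

eca_backward <- function(X, w, dY, cache, L) {
  dgate <- nn_block_dot(X, dY, L)
  ds <- dgate * cache$gate * (1 - cache$gate)
  k <- length(w)
  offs <- seq_len(k) - (k + 1) / 2
  dw <- numeric(k)
  davg <- matrix(0, nrow(ds), ncol(ds))
  for (t in seq_len(k)) {
    dw[t] <- sum(ds * shift_mat_rows(cache$avg, offs[t]))
    davg <- davg + w[t] * shift_mat_rows(ds, -offs[t])
  }
  dX <- nn_scale_blocks(dY, cache$gate, L) +
    nn_scale_blocks(matrix(1, nrow(X), ncol(X)), davg / L, L)
  list(dX = dX, dw = dw)
}

# Instance normalization over time, per window and channel, with a
# learnable per-channel affine. Makes the forward pass invariant to the
# scale of the convolution weights, which is what keeps the cascade from
# drifting into sigmoid saturation under region-overlap losses.
inorm_forward <- function(X, gamma, beta, L, eps = 1e-5) {
  mu <- nn_block_means(X, L)                          # C x Nb
  Xc <- nn_add_blocks(X, -mu, L)
  v <- nn_block_dot(Xc, Xc, L) / L
  inv <- 1 / sqrt(v + eps)
  xhat <- nn_scale_blocks(Xc, inv, L)
  list(Y = xhat * gamma + beta, xhat = xhat, inv = inv)
}

inorm_backward <- function(dY, gamma, cache, L) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxh <- dY * gamma
  m1 <- nn_block_means(dxh, L)                        # mean_t(dxh)
  m2 <- nn_block_dot(dxh, xhat, L) / L                # mean_t(dxh * xhat)
  dX <- nn_scale_blocks(
    nn_add_blocks(dxh - xhat * nn_scale_blocks(matrix(1, nrow(xhat),
                                                      ncol(xhat)), m2, L),
                  -m1, L),
    cache$inv, L)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}
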