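# Training losses. Matrices are channels-first (3 x N, or 3 x (L*Nb) for a
# batch); *_core versions also return analytic gradients for
# backpropagation. Loss masks are length-N 0/1 vectors over time.

dice_core <- function(P, Tg, M = NULL, eps = 1) {
  if (!is.null(M)) {
    Mx <- rep(M, each = nrow(P))
    P <- P * Mx; Tg <- Tg * Mx
  }
  inter <- rowSums(P * Tg)
  sums <- rowSums(P) + rowSums(Tg)
  d <- (2 * inter + eps) / (sums + eps)
  loss <- 1 - mean(d)
  grad <- function() {
    C <- length(d)
    denom <- sums + eps              # length C, recycles down columns
    num <- 2 * inter + eps
    dP <- -((2 * Tg) * denom - num) / denom^2 / C
    if (!is.null(M)) dP <- dP * rep(M, each = nrow(P))
    dP
  }
  list(loss = loss, dice = d, grad = grad)
}

# batched per-window soft Dice: windows are length-L column blocks; the
# Dice of each (window, channel) pair is computed separately (the eps = 1
# smoothing then stabilizes windows whose channel is empty) and the loss is
# one minus their mean
dice_batch_core <- function(P, Tg, M = NULL, L = ncol(P), eps = 1) {
  if (!is.null(M)) {
    Mx <- rep(M, each = nrow(P))
    P <- P * Mx
    Tg <- Tg * Mx
  }
  inter <- nn_block_dot(P, Tg, L)              # C x Nb sums of p*t
  sp <- nn_block_means(P, L) * L
  st <- nn_block_means(Tg, L) * L
  num <- 2 * inter + eps
  denom <- sp + st + eps
  d <- num / denom                             # C x Nb per-window Dice
  loss <- 1 - mean(d)
  grad <- function() {
    k <- length(d)
    ones <- matrix(1, nrow(P), ncol(P))
    dP <- (-2 * nn_scale_blocks(Tg, 1 / denom, L) +
             nn_scale_blocks(ones, num / denom^2, L)) / k
    if (!is.null(M)) dP <- dP * rep(M, each = nrow(P))
    dP
  }
  list(loss = loss, dice = rowMeans(d), grad = grad)
}

#' Soft Dice loss
#'
#' Per-channel soft Dice `D_c = (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`
#' with `eps = 1` (stabilizes windows whose channel is empty, e.g. the
#' stimulation channel of unpaced cycles); the loss is `1 - mean_c(D_c)`.
#' Bounded in `[0, 1]` and 0 at perfect prediction (up to the `eps` effect).
#'
#' @param pred 3xN prediction in `[0, 1]`.
#' @param target 3xN binary reference mask.
#' @param loss_mask optional length-N 0/1 vector; zero positions (padding)
#'   are excluded from all sums.
#' @param eps smoothing constant, default 1.
#' @return scalar loss.
#' @export
dice_loss <- function(pred, target, loss_mask = NULL, eps = 1) {
  if (!all(dim(pred) == dim(target)))
    stop("pred and target must have identical shape")
  dice_core(pred, target, loss_mask, eps)$loss
}

moving_sum <- function(x, half) {
  # sum over window [i-half, i+half] per column, zero-padded
  cs <- apply(rbind(0, x), 2, cumsum)
  n <- nrow(x)
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1)
  cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
}

edge_map <- function(X) {
  # |first difference| along rows; last row padded with 0
  n <- nrow(X)
  E <- abs(X[-1, , drop = FALSE] - X[-n, , drop = FALSE])
  rbind(E, 0)
}

sens_core <- function(P, Tg, tol, eps = 1e-7) {
  n <- nrow(P)
  pe <- edge_map(P)
  te <- edge_map(Tg)
  if (sum(te) == 0) {
    return(list(loss = 0, grad = function() matrix(0, n, ncol(P))))
  }
  dil_t <- pmin(moving_sum(te, tol), 1)       # binary target: dilation
  ms_pe <- moving_sum(pe, tol)
  dil_p <- pmin(ms_pe, 1)                     # soft dilation, clipped
  TP <- sum(pe * dil_t)
  FN <- sum(te * (1 - dil_p))
  S <- TP + FN + eps
  loss <- 1 - (TP + eps) / S   # exactly 0 at perfect prediction
  grad <- function() {
    dTP <- -FN / S^2
    dFN <- (TP + eps) / S^2
    dpe <- dTP * dil_t
    # FN depends on pe through the clipped moving sum
    inner <- te * (ms_pe < 1)
    dpe <- dpe - dFN * moving_sum(inner, tol)
    # back through |diff|
    sgn <- sign(rbind(P[-1, , drop = FALSE] - P[-n, , drop = FALSE], 0))
    d <- dpe * sgn
    dP <- matrix(0, n, ncol(P))
    dP[-n, ] <- -d[-n, , drop = FALSE]
    dP[-1, ] <- dP[-1, , drop = FALSE] + d[-n, , drop = FALSE]
    dP
  }
  list(loss = loss, grad = grad)
}

#' Edge sensitivity loss
#'
#' Differentiable surrogate of the sensitivity score `Se = TP / (TP + FN)`
#' computed on segment boundaries: edge maps are absolute first differences
#' of prediction and target, target edges are dilated by the tolerance, and
#' soft true positives / false negatives are accumulated as
#' `TP = sum(pred_edges * dilated_target_edges)`,
#' `FN = sum(target_edges * (1 - dilated_pred_edges))`. The loss
#' `1 - TP/(TP+FN)` is 0 when every reference boundary has a predicted edge
#' within the tolerance and tends to 1 when all are missed; a target with no
#' edges yields 0 (nothing to miss).
#'
#' @param pred 3xN prediction in `[0, 1]`.
#' @param target 3xN binary reference mask.
#' @param tolerance edge tolerance in samples, default 10.
#' @return scalar loss.
#' @export
sensitivity_loss <- function(pred, target, tolerance = 10) {
  if (!all(dim(pred) == dim(target)))
    stop("pred and target must have identical shape")
  sens_core(t(pred), t(target), tolerance)$loss
}
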