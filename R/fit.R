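#' Turn a labeled trace into a fixed-length training window
#'
#' Windows are 1024 samples (about one second at 1000 Hz, divisible by
#' `2^5` and `2^6` so both supported depths apply). Shorter traces are
#' zero-padded symmetrically and the padding is excluded from the loss via
#' the window's loss mask; longer traces are linearly resampled to the
#' window length (with their interval coordinates rescaled alike). Signals
#' are standardized to `[-1, 1]` by max-abs scaling, matching the
#' normalization of the synthetic segments.
#'
#' @param trace an `egm_trace`.
#' @param window_len window length in samples, default 1024.
#' @return list with `x` (length-W signal), `y` (3 x W target mask), `m`
#'   (length-W loss mask).
#' @export
window_trace <- function(trace, window_len = 1024) {
  n <- trace$n
  sig <- trace$signal
  if (n == window_len) {
    y <- trace$mask
    m <- rep(1, window_len)
  } else if (n < window_len) {
    pad_l <- (window_len - n) %/% 2
    pad_r <- window_len - n - pad_l
    sig <- c(numeric(pad_l), sig, numeric(pad_r))
    y <- cbind(matrix(0L, 3, pad_l), trace$mask, matrix(0L, 3, pad_r))
    m <- c(numeric(pad_l), rep(1, n), numeric(pad_r))
  } else {
    f <- window_len / n
    sig <- interp_to_length(sig, window_len)
    ints <- trace$intervals
    ints$onset <- floor(ints$onset * f)
    ints$offset <- pmax(ceiling(ints$offset * f), ints$onset + 1)
    ints <- clip_intervals(ints, 0, window_len)
    y <- intervals_to_mask(ints, window_len)
    m <- rep(1, window_len)
  }
  peak <- max(abs(sig))
  if (peak > 0) sig <- sig / peak
  list(x = sig, y = y, m = m)
}

stack_windows <- function(windows) {
  list(X = matrix(unlist(lapply(windows, `[[`, "x")), nrow = 1),
       Y = do.call(cbind, lapply(windows, `[[`, "y")),
       M = unlist(lapply(windows, `[[`, "m")))
}

#' Patient-disjoint train/test split
#'
#' The split fraction applies to patients, never to traces: all traces of a
#' patient land on the same side.
#'
#' @param traces list of traces, each with a `patient` element.
#' @param fraction fraction of patients assigned to training, default 0.75.
#' @param seed integer seed for the patient shuffle.
#' @return list with `train` and `test` trace lists.
#' @export
split_by_patient <- function(traces, fraction = 0.75, seed = 123456) {
  patients <- vapply(traces, function(tr) tr$patient, character(1))
  ids <- unique(patients)
  if (length(ids) < 2) stop("need at least 2 patients for a patient-wise split")
  set.seed(seed)
  train_ids <- sample(ids, round(fraction * length(ids)))
  list(train = traces[patients %in% train_ids],
       test = traces[!patients %in% train_ids])
}

adam_init <- function(net) {
  st <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    if (nd$op == "conv") {
      st[[i]] <- list(mW = lapply(nd$W, function(w) w * 0),
                      vW = lapply(nd$W, function(w) w * 0),
                      mb = nd$b * 0, vb = nd$b * 0)
    } else if (nd$op == "inorm") {
      st[[i]] <- list(mg = nd$gamma * 0, vg = nd$gamma * 0,
                      mbt = nd$beta * 0, vbt = nd$beta * 0)
    } else if (nd$op == "eca") {
      st[[i]] <- list(mw = nd$w * 0, vw = nd$w * 0)
    }
  }
  st
}

copy_nodes <- function(nodes) {
  lapply(nodes, function(nd) {
    if (!is.null(nd$W)) nd$W <- lapply(nd$W, function(w) w + 0)
    if (!is.null(nd$b)) nd$b <- nd$b + 0
    if (!is.null(nd$w)) nd$w <- nd$w + 0
    if (!is.null(nd$gamma)) nd$gamma <- nd$gamma + 0
    if (!is.null(nd$beta)) nd$beta <- nd$beta + 0
    nd
  })
}

grad_global_norm <- function(grads) {
  total <- 0
  for (gi in grads) {
    if (is.null(gi)) next
    if (!is.null(gi$dW)) {
      total <- total + sum(vapply(gi$dW, function(w) sum(w * w), numeric(1)))
      total <- total + sum(gi$db * gi$db)
    }
    if (!is.null(gi$dw)) total <- total + sum(gi$dw * gi$dw)
    if (!is.null(gi$dgamma))
      total <- total + sum(gi$dgamma^2) + sum(gi$dbeta^2)
  }
  sqrt(total)
}

scale_grads <- function(grads, f) {
  for (i in seq_along(grads)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    if (!is.null(gi$dW)) {
      gi$dW <- lapply(gi$dW, `*`, f)
      gi$db <- gi$db * f
    }
    if (!is.null(gi$dw)) gi$dw <- gi$dw * f
    if (!is.null(gi$dgamma)) {
      gi$dgamma <- gi$dgamma * f
      gi$dbeta <- gi$dbeta * f
    }
    grads[[i]] <- gi
  }
  grads
}

# Adam updates run in place through the compiled kernel: the weight and
# moment tensors are owned exclusively by the network being trained and its
# optimizer state, so in-place mutation is safe and avoids reallocating the
# full parameter set every step.
adam_step <- function(net, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$nodes)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    nd <- net$nodes[[i]]
    if (nd$op == "conv") {
      for (tap in seq_along(nd$W))
        nn_adam_inplace(nd$W[[tap]], gi$dW[[tap]], state[[i]]$mW[[tap]],
                        state[[i]]$vW[[tap]], lr, t, b1, b2, eps)
      nn_adam_inplace(nd$b, gi$db, state[[i]]$mb, state[[i]]$vb,
                      lr, t, b1, b2, eps)
    } else if (nd$op == "inorm") {
      nn_adam_inplace(nd$gamma, gi$dgamma, state[[i]]$mg, state[[i]]$vg,
                      lr, t, b1, b2, eps)
      nn_adam_inplace(nd$beta, gi$dbeta, state[[i]]$mbt, state[[i]]$vbt,
                      lr, t, b1, b2, eps)
    } else if (nd$op == "eca") {
      nn_adam_inplace(nd$w, gi$dw, state[[i]]$mw, state[[i]]$vw,
                      lr, t, b1, b2, eps)
    }
  }
  invisible(NULL)
}

batch_loss_and_grad <- function(net, batch, L, weights, tol, train = TRUE) {
  fw <- net_forward(net, batch$X, L, train = train)
  P <- fw$vals[[net$out]]
  dc <- dice_batch_core(P, batch$Y, batch$M, L)
  loss <- weights[["dice"]] * dc$loss
  dP <- if (weights[["dice"]] > 0) weights[["dice"]] * dc$grad()
        else matrix(0, nrow(P), ncol(P))
  if (weights[["sens"]] > 0) {
    nb <- ncol(P) / L
    sl <- 0
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * L + 1):(b * L)
      sc <- sens_core(t(P[, idx, drop = FALSE]),
                      t(batch$Y[, idx, drop = FALSE]), tol)
      sl <- sl + sc$loss / nb
      dP[, idx] <- dP[, idx] + weights[["sens"]] * t(sc$grad()) / nb
    }
    loss <- loss + weights[["sens"]] * sl
  }
  list(loss = loss, dice = dc$dice, fw = fw, dP = dP)
}

#' Fit an electrogram segmentation network
#'
#' The central fitting function of the package: trains a 1D U-Net or W-Net
#' to map a standardized single-lead electrogram window to per-sample
#' probabilities of the three component classes (stimulation artifact,
#' local field, far field). The training protocol is fixed and fully seeded: Adam,
#' leaky rectifiers, base width 32 doubled per level, batch-wise soft Dice
#' loss optionally combined with the edge sensitivity loss, spatial dropout
#' regularization, and a fixed seed (123456) for full reproducibility --
#' two runs with identical inputs and seed produce identical weights.
#' Training is intended to run on synthetic labeled traces from
#' [generate_dataset()].
#'
#' @param traces list of `egm_trace` objects (the training set).
#' @param arch,depth,base_channels,blocks_per_level,kernel_size,use_eca,dropout
#'   passed to [net_config()].
#' @param epochs training epochs.
#' @param batch_size windows per optimization step, default 16.
#' @param learning_rate Adam step size, default 4e-3.
#' @param loss_weights named weights `c(dice=, sens=)`; the best-performing
#'   configuration trains with the Dice loss alone.
#' @param edge_tolerance sensitivity-loss edge tolerance (samples).
#' @param seed reproducibility seed, default 123456.
#' @param clip_norm global gradient-norm clipping threshold (stabilizes the
#'   region-overlap loss late in training); `Inf` disables.
#' @param lr_schedule `"cosine"` (default) anneals the step size from
#'   `learning_rate` down to 5% of it over the run, which sharpens the
#'   late-training fit; `"constant"` disables annealing.
#' @param validation_split fraction of patients carved out of the training
#'   set for checkpoint selection (0 disables validation; the returned model
#'   then carries the final weights).
#' @param window_len training window length, default 1024.
#' @param verbose print a line every 20 epochs.
#' @return an object of class `egm_segmenter` with elements `net`,
#'   `history` (per-epoch data.frame), `train_config` and `window_len`.
#' @seealso [predict.egm_segmenter()], [model_dice()]
#' @export
egm_segmenter <- function(traces, arch = "unet", depth = 5,
                          base_channels = 32, blocks_per_level = 2,
                          kernel_size = 3, use_eca = FALSE, dropout = 0.25,
                          epochs = 50, batch_size = 16, learning_rate = 4e-3,
                          loss_weights = c(dice = 1, sens = 0),
                          edge_tolerance = 10, seed = 123456,
                          validation_split = 0, window_len = 1024,
                          clip_norm = 1,
                          lr_schedule = c("cosine", "constant"),
                          verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(length(traces) >= 1)
  if (any(loss_weights < 0) || all(loss_weights == 0))
    stop("loss weights must be non-negative and not both zero")
  set.seed(seed)
  cfg <- net_config(arch = arch, depth = depth, base_channels = base_channels,
                    blocks_per_level = blocks_per_level,
                    kernel_size = kernel_size, use_eca = use_eca,
                    dropout = dropout)
  net <- build_model(cfg)
  val_traces <- list()
  if (validation_split > 0 &&
      length(unique(vapply(traces, `[[`, character(1), "patient"))) >= 2) {
    sp <- split_by_patient(traces, fraction = 1 - validation_split, seed = seed)
    traces <- sp$train; val_traces <- sp$test
  }
  windows <- lapply(traces, window_trace, window_len = window_len)
  val_batch <- if (length(val_traces))
    stack_windows(lapply(val_traces, window_trace, window_len = window_len))
  state <- adam_init(net)
  nw <- length(windows)
  history <- vector("list", epochs)
  best <- list(dice = -Inf, nodes = NULL)
  total_steps <- epochs * length(seq(1, nw, by = batch_size))
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(nw)
    starts <- seq(1, nw, by = batch_size)
    ep_loss <- 0; ep_dice <- numeric(3)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, nw)]
      batch <- stack_windows(windows[idx])
      bl <- batch_loss_and_grad(net, batch, window_len, loss_weights,
                                edge_tolerance, train = TRUE)
      if (!is.finite(bl$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      grads <- net_backward(net, bl$fw, bl$dP)
      if (is.finite(clip_norm) && clip_norm > 0) {
        gn <- grad_global_norm(grads)
        if (gn > clip_norm) grads <- scale_grads(grads, clip_norm / gn)
      }
      step <- step + 1
      lr_t <- if (lr_schedule == "cosine") {
        eta_min <- learning_rate / 20
        eta_min + 0.5 * (learning_rate - eta_min) *
          (1 + cos(pi * (step - 1) / max(1, total_steps - 1)))
      } else learning_rate
      adam_step(net, grads, state, lr_t, step)
      w <- length(idx) / nw
      ep_loss <- ep_loss + bl$loss * w
      ep_dice <- ep_dice + unname(bl$dice) * w
    }
    row <- data.frame(epoch = ep, loss = ep_loss,
                      dice_stim = ep_dice[1], dice_lf = ep_dice[2],
                      dice_ff = ep_dice[3], val_loss = NA_real_,
                      val_dice = NA_real_)
    if (length(val_traces)) {
      vfw <- net_forward(net, val_batch$X, window_len, train = FALSE)
      vdc <- dice_batch_core(vfw$vals[[net$out]], val_batch$Y, val_batch$M,
                             window_len)
      row$val_loss <- vdc$loss
      row$val_dice <- mean(vdc$dice)
      if (row$val_dice > best$dice)  # deep-copy: training mutates in place
        best <- list(dice = row$val_dice, nodes = copy_nodes(net$nodes))
    }
    history[[ep]] <- row
    if (verbose && (ep %% 20 == 0 || ep == 1))
      message(sprintf("epoch %d/%d  loss %.4f  dice %s", ep, epochs, ep_loss,
                      paste(sprintf("%.3f", ep_dice), collapse = "/")))
  }
  if (!is.null(best$nodes)) net$nodes <- best$nodes
  structure(list(
    net = net,
    history = do.call(rbind, history),
    train_config = list(epochs = epochs, batch_size = batch_size,
                        learning_rate = learning_rate,
                        loss_weights = loss_weights,
                        edge_tolerance = edge_tolerance, seed = seed,
                        clip_norm = clip_norm, lr_schedule = lr_schedule,
                        validation_split = validation_split,
                        n_train_traces = length(traces),
                        n_val_traces = length(val_traces)),
    window_len = window_len), class = "egm_segmenter")
}

prepare_windows <- function(object, newdata) {
  W <- object$window_len
  if (inherits(newdata, "egm_trace")) newdata <- list(newdata)
  if (is.list(newdata) && all(vapply(newdata, inherits, logical(1), "egm_trace"))) {
    x <- t(vapply(newdata, function(tr) window_trace(tr, W)$x, numeric(W)))
  } else if (is.null(dim(newdata))) {
    x <- matrix(newdata, 1)
  } else {
    x <- as.matrix(newdata)
  }
  peaks <- apply(abs(x), 1, max)
  peaks[peaks == 0] <- 1
  x / peaks
}

#' Predict component probabilities, masks or intervals
#'
#' @param object a fitted `egm_segmenter`.
#' @param newdata an `egm_trace`, a list of traces, a numeric window, or a
#'   matrix with one window per row. Windows are max-abs standardized
#'   internally.
#' @param type `"prob"` (3xN probability maps), `"mask"` (binarized 3xN
#'   masks) or `"intervals"` (interval tables after mask cleanup).
#' @param threshold binarization threshold for masks/intervals, default 0.5.
#' @param ... unused.
#' @return a single result (matrix or interval table) for single-window
#'   input, else a list of results.
#' @export
predict.egm_segmenter <- function(object, newdata, type = c("prob", "mask",
                                                            "intervals"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- prepare_windows(object, newdata)
  single <- nrow(x) == 1 &&
    (is.null(dim(newdata)) || inherits(newdata, "egm_trace"))
  probs <- net_predict(object$net, x)
  if (is.matrix(probs)) probs <- list(probs)
  out <- lapply(probs, function(p) switch(type,
    prob = p,
    mask = binarize(p, threshold),
    intervals = mask_to_intervals(binarize(p, threshold))))
  if (single) out[[1]] else out
}

#' Hard Dice of a fitted model on labeled traces
#'
#' Binarizes the model's predictions and computes the per-channel hard Dice
#' score against the traces' ground-truth masks, plus the merged local+far
#' field class (the OR of the LF and FF channels), all in percent.
#'
#' @param object a fitted `egm_segmenter`.
#' @param traces list of `egm_trace`s.
#' @param threshold binarization threshold.
#' @return named numeric: `STIM`, `LF`, `FF`, `merged_LF_FF` (percent).
#' @export
model_dice <- function(object, traces, threshold = 0.5) {
  W <- object$window_len
  wins <- lapply(traces, window_trace, window_len = W)
  x <- t(vapply(wins, `[[`, numeric(W), "x"))
  probs <- net_predict(object$net, x)
  if (is.matrix(probs)) probs <- list(probs)
  pred <- do.call(cbind, lapply(probs, binarize, threshold = threshold))
  gt <- do.call(cbind, lapply(wins, `[[`, "y"))
  msk <- unlist(lapply(wins, `[[`, "m"))
  pred <- pred[, msk > 0, drop = FALSE]
  gt <- gt[, msk > 0, drop = FALSE]
  d <- sample_dice(pred, gt)
  merged <- sample_dice(matrix(pmin(pred[2, ] + pred[3, ], 1), 1),
                        matrix(pmin(gt[2, ] + gt[3, ], 1), 1))
  c(d, merged_LF_FF = unname(merged))
}

#' @export
print.egm_segmenter <- function(x, ...) {
  cfg <- x$net$config
  cat(sprintf("<egm_segmenter> %s (depth %d, base %d%s), %s parameters\n",
              toupper(cfg$arch), cfg$depth, cfg$base_channels,
              if (cfg$use_eca) ", ECA" else "",
              format(n_parameters(x$net), big.mark = ",")))
  h <- x$history
  cat(sprintf("  trained %d epochs on %d traces; final loss %.4f, soft Dice %.3f/%.3f/%.3f (STIM/LF/FF)\n",
              nrow(h), x$train_config$n_train_traces, h$loss[nrow(h)],
              h$dice_stim[nrow(h)], h$dice_lf[nrow(h)], h$dice_ff[nrow(h)]))
  invisible(x)
}

#' @export
summary.egm_segmenter <- function(object, ...) {
  print(object)
  cat("  training configuration:\n")
  tc <- object$train_config
  cat(sprintf("    batch %d, lr %g, loss weights dice=%g sens=%g, seed %d\n",
              tc$batch_size, tc$learning_rate, tc$loss_weights[["dice"]],
              tc$loss_weights[["sens"]], tc$seed))
  invisible(object)
}

#' @export
coef.egm_segmenter <- function(object, ...) flatten_params(object$net)

#' Plot the training history
#'
#' @param x a fitted `egm_segmenter`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.egm_segmenter <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, 1 - h$dice_lf, 1 - h$dice_ff),
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss",
                    col = c("black", "forestgreen", "magenta"), ...)
  graphics::legend("topright", c("total", "1 - Dice LF", "1 - Dice FF"),
                   lty = 1, col = c("black", "forestgreen", "magenta"),
                   bty = "n")
  invisible(x)
}
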