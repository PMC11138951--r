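#' Segmentation network configuration
#'
#' Hyperparameters of the 1D encoder-decoder networks. The encoder doubles
#' its channel count at every pooling (level i holds
#' `base_channels * 2^(i-1)` filters), the decoder halves it at every
#' upsampling; pooling and upsampling use kernel size 2. The W-Net chains
#' two U-Nets: the second takes the (sigmoid) output of the first as input
#' and receives cross skip connections from the first decoder's levels into
#' its own encoder. Valid input lengths are multiples of `2^(depth-1)`.
#'
#' @param arch `"unet"` or `"wnet"`.
#' @param depth number of resolution levels (5 or 6 in the configurations
#'   this package targets).
#' @param base_channels filters at the first level, default 32.
#' @param blocks_per_level convolutional blocks per level, default 2.
#' @param kernel_size odd convolution kernel size, default 3.
#' @param use_eca add an efficient-channel-attention block after each
#'   convolutional block.
#' @param use_norm apply per-window channel (instance) normalization with a
#'   learnable affine after each convolution. Normalization makes the
#'   cascade scale-invariant; without it, region-overlap losses drive the
#'   unnormalized network into sigmoid saturation late in training.
#' @param in_channels,out_channels input leads and output classes (1 and 3).
#' @param lrelu_slope negative slope of the leaky rectifier, default 0.01.
#' @param dropout spatial (channel-wise) dropout rate inside convolutional
#'   blocks, default 0.25; set 0 to disable.
#' @return list of class `net_config`.
#' @export
net_config <- function(arch = c("unet", "wnet"), depth = 5,
                       base_channels = 32, blocks_per_level = 2,
                       kernel_size = 3, use_eca = FALSE, use_norm = TRUE,
                       in_channels = 1, out_channels = 3,
                       lrelu_slope = 0.01, dropout = 0.25) {
  arch <- match.arg(arch)
  stopifnot(depth >= 1, base_channels >= 1, kernel_size %% 2 == 1,
            dropout >= 0, dropout < 1)
  structure(list(arch = arch, depth = depth, base_channels = base_channels,
                 blocks_per_level = blocks_per_level,
                 kernel_size = kernel_size, use_eca = use_eca,
                 use_norm = use_norm,
                 in_channels = in_channels, out_channels = out_channels,
                 lrelu_slope = lrelu_slope, dropout = dropout),
            class = "net_config")
}

new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

add_node <- function(g, op, inputs = integer(0), ...) {
  g$nodes[[length(g$nodes) + 1L]] <- c(list(op = op, inputs = inputs),
                                       list(...))
  length(g$nodes)
}

# one convolutional block: conv -> leaky ReLU (+ ECA) (+ spatial dropout)
add_conv_block <- function(g, input, cin, cout, cfg, with_extras = TRUE) {
  cur <- add_node(g, "conv", input,
                  W = he_init(cfg$kernel_size, cin, cout, cfg$lrelu_slope),
                  b = numeric(cout))
  if (isTRUE(cfg$use_norm))
    cur <- add_node(g, "inorm", cur, gamma = rep(1, cout),
                    beta = numeric(cout))
  cur <- add_node(g, "lrelu", cur, slope = cfg$lrelu_slope)
  if (with_extras && cfg$use_eca) {
    kc <- eca_kernel_size(cout)
    cur <- add_node(g, "eca", cur, w = stats::rnorm(kc, sd = 0.1), L_div = NA)
  }
  if (with_extras && cfg$dropout > 0)
    cur <- add_node(g, "dropout", cur, rate = cfg$dropout)
  cur
}

build_unet_graph <- function(g, input, in_ch, cfg, cross_in = NULL) {
  base <- cfg$base_channels
  skips <- integer(cfg$depth)
  cur <- input; cur_ch <- in_ch
  for (lev in seq_len(cfg$depth)) {
    ch <- base * 2^(lev - 1)
    if (!is.null(cross_in) && lev < cfg$depth && !is.na(cross_in$ids[lev])) {
      cur <- add_node(g, "concat", c(cur, cross_in$ids[lev]))
      cur_ch <- cur_ch + cross_in$channels[lev]
    }
    for (blk in seq_len(cfg$blocks_per_level)) {
      cur <- add_conv_block(g, cur, cur_ch, ch, cfg)
      cur_ch <- ch
    }
    skips[lev] <- cur
    if (lev < cfg$depth) cur <- add_node(g, "pool", cur)
  }
  dec_feats <- rep(NA_integer_, cfg$depth)
  for (lev in seq.int(cfg$depth - 1, 1)) {
    ch <- base * 2^(lev - 1)
    cur <- add_node(g, "up", cur)
    cur <- add_conv_block(g, cur, cur_ch, ch, cfg, with_extras = FALSE)
    cur <- add_node(g, "concat", c(cur, skips[lev]))
    cur_ch <- 2 * ch
    for (blk in seq_len(cfg$blocks_per_level)) {
      cur <- add_conv_block(g, cur, cur_ch, ch, cfg)
      cur_ch <- ch
    }
    dec_feats[lev] <- cur
  }
  list(out = cur, out_ch = cur_ch, dec_feats = dec_feats)
}

#' Build a segmentation network
#'
#' Instantiates a 1D U-Net or W-Net per the configuration, with randomly
#' initialized weights (He initialization matched to the leaky rectifier;
#' deterministic given the RNG state). The final layer is a 1x1 convolution
#' to `out_channels` per-sample outputs squashed to `[0, 1]` by a sigmoid.
#'
#' @param config a [net_config()].
#' @return object of class `egm_net`.
#' @export
build_model <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  g <- new_graph()
  input <- add_node(g, "input")
  u1 <- build_unet_graph(g, input, config$in_channels, config)
  head1 <- add_node(g, "conv", u1$out,
                    W = he_init(1, u1$out_ch, config$out_channels),
                    b = numeric(config$out_channels))
  out <- add_node(g, "sigmoid", head1)
  if (config$arch == "wnet") {
    base <- config$base_channels
    cross <- list(ids = u1$dec_feats,
                  channels = base * 2^(seq_len(config$depth) - 1))
    u2 <- build_unet_graph(g, out, config$out_channels, config, cross)
    head2 <- add_node(g, "conv", u2$out,
                      W = he_init(1, u2$out_ch, config$out_channels),
                      b = numeric(config$out_channels))
    out <- add_node(g, "sigmoid", head2)
  }
  structure(list(nodes = g$nodes, out = out, config = config),
            class = "egm_net")
}

#' Number of trainable parameters
#' @param net an `egm_net`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  total <- 0
  for (nd in net$nodes) {
    if (nd$op == "conv")
      total <- total + sum(vapply(nd$W, length, numeric(1))) + length(nd$b)
    if (nd$op == "inorm") total <- total + length(nd$gamma) + length(nd$beta)
    if (nd$op == "eca") total <- total + length(nd$w)
  }
  total
}

net_forward <- function(net, X, L, train = FALSE) {
  depth <- net$config$depth
  if (L %% 2^(depth - 1) != 0)
    stop("input length ", L, " is not divisible by 2^(depth-1) = ",
         2^(depth - 1))
  nn <- length(net$nodes)
  vals <- vector("list", nn)
  caches <- vector("list", nn)
  lens <- numeric(nn)
  for (i in seq_len(nn)) {
    nd <- net$nodes[[i]]
    inp <- nd$inputs
    switch(nd$op,
      input = { vals[[i]] <- X; lens[i] <- L },
      conv = {
        lens[i] <- lens[inp]
        vals[[i]] <- nn_conv_fwd(vals[[inp]], nd$W, nd$b, lens[i],
                                 exact_blocks = !train)
      },
      lrelu = {
        lens[i] <- lens[inp]
        vals[[i]] <- nn_lrelu_fwd(vals[[inp]], nd$slope)
      },
      pool = {
        lens[i] <- lens[inp] / 2
        mp <- nn_pool_fwd(vals[[inp]])
        vals[[i]] <- mp$Y
        caches[[i]] <- mp$amax
      },
      up = {
        lens[i] <- lens[inp] * 2
        vals[[i]] <- nn_up_fwd(vals[[inp]])
      },
      concat = {
        lens[i] <- lens[inp[1]]
        vals[[i]] <- nn_rbind2(vals[[inp[1]]], vals[[inp[2]]])
      },
      inorm = {
        lens[i] <- lens[inp]
        io <- nn_inorm_fwd(vals[[inp]], nd$gamma, nd$beta, lens[i], 1e-5)
        vals[[i]] <- io$Y
        caches[[i]] <- io
      },
      dropout = {
        lens[i] <- lens[inp]
        if (train && nd$rate > 0) {
          Xi <- vals[[inp]]
          Nb <- ncol(Xi) %/% lens[i]
          keep <- matrix(stats::rbinom(nrow(Xi) * Nb, 1, 1 - nd$rate),
                         nrow(Xi), Nb) / (1 - nd$rate)
          vals[[i]] <- nn_scale_blocks(Xi, keep, lens[i])
          caches[[i]] <- keep
        } else vals[[i]] <- vals[[inp]]
      },
      eca = {
        lens[i] <- lens[inp]
        ec <- eca_forward(vals[[inp]], nd$w, lens[i])
        vals[[i]] <- ec$Y
        caches[[i]] <- ec
      },
      sigmoid = {
        # pre-activations are clamped to +/-12 so that saturated outputs
        # keep a small nonzero gradient and training can recover from
        # all-background collapses of the region-overlap loss
        lens[i] <- lens[inp]
        vals[[i]] <- nn_sigmoid_fwd(vals[[inp]], 12)
      },
      stop("unknown op ", nd$op))
  }
  list(vals = vals, caches = caches, lens = lens, train = train)
}

net_backward <- function(net, fw, dOut) {
  nn <- length(net$nodes)
  g <- vector("list", nn)
  grads <- vector("list", nn)
  g[[net$out]] <- dOut
  addg <- function(j, d) {
    g[[j]] <<- if (is.null(g[[j]])) d else g[[j]] + d
  }
  for (i in seq.int(nn, 1)) {
    gi <- g[[i]]
    if (is.null(gi)) next
    nd <- net$nodes[[i]]
    inp <- nd$inputs
    switch(nd$op,
      input = NULL,
      conv = {
        bk <- nn_conv_bwd(fw$vals[[inp]], nd$W, gi, fw$lens[i])
        grads[[i]] <- list(dW = bk$dW, db = bk$db)
        addg(inp, bk$dX)
      },
      lrelu = addg(inp, nn_lrelu_bwd(fw$vals[[inp]], gi, nd$slope)),
      pool = addg(inp, nn_pool_bwd(gi, fw$caches[[i]])),
      up = addg(inp, nn_up_bwd(gi)),
      concat = {
        c1 <- nrow(fw$vals[[inp[1]]])
        addg(inp[1], nn_row_slice(gi, 1, c1))
        addg(inp[2], nn_row_slice(gi, c1 + 1, nrow(gi)))
      },
      inorm = {
        bk <- nn_inorm_bwd(gi, nd$gamma, fw$caches[[i]]$xhat,
                           fw$caches[[i]]$inv, fw$lens[i])
        grads[[i]] <- list(dgamma = bk$dgamma, dbeta = bk$dbeta)
        addg(inp, bk$dX)
      },
      dropout = {
        if (fw$train && !is.null(fw$caches[[i]]))
          addg(inp, nn_scale_blocks(gi, fw$caches[[i]], fw$lens[i]))
        else addg(inp, gi)
      },
      eca = {
        bk <- eca_backward(fw$vals[[inp]], nd$w, gi, fw$caches[[i]], fw$lens[i])
        grads[[i]] <- list(dw = bk$dw)
        addg(inp, bk$dX)
      },
      sigmoid = addg(inp, nn_sigmoid_bwd(fw$vals[[i]], gi)))
    g[i] <- list(NULL)  # free as we go without shrinking the list
  }
  grads
}

#' Run a network on input windows
#'
#' @param net an `egm_net`.
#' @param x numeric vector (one window) or matrix with one window per row;
#'   window length must be divisible by `2^(depth-1)`. Inputs are expected
#'   max-abs standardized to `[-1, 1]`.
#' @return for a single window, a 3xN probability matrix (rows STIM/LF/FF);
#'   for a matrix input, a list of such matrices. Outputs lie in `[0, 1]`
#'   and are deterministic (evaluation mode).
#' @export
net_predict <- function(net, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, 1)
  L <- ncol(x)
  Nb <- nrow(x)
  X <- matrix(as.numeric(t(x)), nrow = net$config$in_channels)
  fw <- net_forward(net, X, L, train = FALSE)
  out <- fw$vals[[net$out]]
  res <- lapply(seq_len(Nb), function(b) {
    m <- out[, ((b - 1) * L + 1):(b * L), drop = FALSE]
    rownames(m) <- MASK_CHANNELS[seq_len(nrow(m))]
    m
  })
  if (single) res[[1]] else res
}

#' @export
print.egm_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<egm_net> %s, depth %d, base %d channels%s, %s parameters\n",
              toupper(cfg$arch), cfg$depth, cfg$base_channels,
              if (cfg$use_eca) " + ECA" else "",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

flatten_params <- function(net) {
  out <- list()
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    if (nd$op == "conv") {
      for (t in seq_along(nd$W)) out[[sprintf("n%d.W%d", i, t)]] <- nd$W[[t]]
      out[[sprintf("n%d.b", i)]] <- nd$b
    } else if (nd$op == "inorm") {
      out[[sprintf("n%d.gamma", i)]] <- nd$gamma
      out[[sprintf("n%d.beta", i)]] <- nd$beta
    } else if (nd$op == "eca") {
      out[[sprintf("n%d.w", i)]] <- nd$w
    }
  }
  out
}
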