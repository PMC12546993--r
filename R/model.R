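# Model assembly: configuration, weight initialisation, the two-stream
# forward pass with recurrent fusion, and full reverse-mode gradients.

#' Model configuration
#'
#' Architecture hyperparameters for the forecaster and its ablation
#' variants. Each stream stacks \code{n_blocks} temporal-spatial-temporal
#' sandwiches of causal gated convolutions (kernel \code{kernel}) around a
#' graph-aggregation block; the abundance stream additionally feeds a
#' \code{lstm_layers}-deep recurrent branch (default five layers) whose
#' hidden width defaults to the window length.
#'
#' @param n_taxa number of taxa D (graph nodes).
#' @param window input window length W (>= kernel).
#' @param horizon forecast steps H produced by the head (default 1).
#' @param channels convolution channels per block (default 16).
#' @param kernel temporal kernel size (default 3).
#' @param n_blocks temporal-spatial-temporal sandwiches per stream
#'   (default 2).
#' @param lstm_layers stacked recurrent layers (default 5).
#' @param lstm_hidden recurrent hidden width (default: \code{window}).
#' @param lstm_on_change also attach a recurrent branch to the change
#'   stream (default FALSE).
#' @param seed weight-initialisation seed.
#' @return object of class \code{model_config}.
#' @export
model_config <- function(n_taxa, window, horizon = 1, channels = 16,
                         kernel = 3, n_blocks = 2, lstm_layers = 5,
                         lstm_hidden = window, lstm_on_change = FALSE,
                         seed = 1) {
  n_taxa <- .check_count(n_taxa, "n_taxa", min = 1L)
  window <- .check_count(window, "window", min = 2L)
  horizon <- .check_count(horizon, "horizon", min = 1L)
  channels <- .check_count(channels, "channels", min = 1L)
  kernel <- .check_count(kernel, "kernel", min = 1L)
  n_blocks <- .check_count(n_blocks, "n_blocks", min = 1L)
  lstm_layers <- .check_count(lstm_layers, "lstm_layers", min = 1L)
  lstm_hidden <- .check_count(lstm_hidden, "lstm_hidden", min = 1L)
  if (kernel > window)
    .stopf("kernel (%d) must not exceed window (%d)", kernel, window)
  structure(list(n_taxa = n_taxa, window = window, horizon = horizon,
                 channels = channels, kernel = kernel, n_blocks = n_blocks,
                 lstm_layers = lstm_layers, lstm_hidden = lstm_hidden,
                 lstm_on_change = isTRUE(lstm_on_change),
                 seed = as.integer(seed)),
            class = "model_config")
}

.VARIANTS <- c("microstnet", "stgcn2s", "lstm")

.uinit <- function(dims, a) array(stats::runif(prod(dims), -a, a), dims)

.init_temporal <- function(cin, cout, k, activation = "glu") {
  c2 <- if (activation == "glu") 2L * cout else cout
  a <- sqrt(6 / (cin * k + c2))
  list(W = .uinit(c(c2, cin, k), a), b = numeric(c2), activation = activation)
}

.init_spatial <- function(cin, cout) {
  a <- sqrt(6 / (cin + cout))
  list(M = .uinit(c(cout, cin), a), b = numeric(cout))
}

.init_stream <- function(cfg) {
  blocks <- list()
  cin <- 1L
  for (s in seq_len(cfg$n_blocks)) {
    blocks <- c(blocks, list(
      list(type = "temporal",
           params = .init_temporal(cin, cfg$channels, cfg$kernel)),
      list(type = "spatial",
           params = .init_spatial(cfg$channels, cfg$channels)),
      list(type = "temporal",
           params = .init_temporal(cfg$channels, cfg$channels, cfg$kernel))))
    cin <- cfg$channels
  }
  blocks
}

.init_lstm <- function(cfg) {
  H <- cfg$lstm_hidden
  a <- 1 / sqrt(H)
  lapply(seq_len(cfg$lstm_layers), function(l) {
    din <- if (l == 1L) 1L else H
    list(Wx = .uinit(c(4L * H, din), a),
         Wh = .uinit(c(4L * H, H), a),
         b = stats::runif(4L * H, -a, a))
  })
}

.feature_width <- function(cfg, variant) {
  sw <- cfg$channels * cfg$window
  switch(variant,
         lstm = cfg$lstm_hidden,
         stgcn2s = 2L * sw,
         microstnet = 2L * sw + cfg$lstm_hidden +
           if (cfg$lstm_on_change) cfg$lstm_hidden else 0L)
}

#' Assemble a model variant
#'
#' \code{microstnet}: both streams plus the recurrent branch, fused.
#' \code{stgcn2s}: the two graph-convolution streams without the recurrent
#' branch. \code{lstm}: the recurrent branch and head only (no graph, no
#' change stream).
#'
#' @param name one of \code{"microstnet"}, \code{"stgcn2s"}, \code{"lstm"}.
#' @param config a [model_config()].
#' @return object of class \code{stnet_model}: list with \code{variant},
#'   \code{config}, \code{params}.
#' @export
build_variant <- function(name, config) {
  name <- match.arg(name, .VARIANTS)
  stopifnot(inherits(config, "model_config"))
  params <- .with_seed(config$seed, {
    p <- list()
    if (name != "lstm") {
      p$stream_a <- .init_stream(config)
      p$stream_c <- .init_stream(config)
    }
    if (name != "stgcn2s") {
      p$lstm <- .init_lstm(config)
      if (config$lstm_on_change && name == "microstnet")
        p$lstm_c <- .init_lstm(config)
    }
    Fw <- .feature_width(config, name)
    a <- sqrt(6 / (Fw + config$horizon))
    p$head <- list(W = .uinit(c(config$horizon, Fw), a),
                   b = numeric(config$horizon))
    p
  })
  structure(list(variant = name, config = config, params = params),
            class = "stnet_model")
}

#' Number of learnable parameters
#'
#' @param model a [build_variant()] model (or a bare parameter list).
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  p <- if (inherits(model, "stnet_model")) model$params else model
  leaves <- rapply(p, length, classes = c("numeric", "array", "matrix"),
                   how = "unlist")
  sum(leaves[!grepl("activation", names(leaves))])
}

# --- forward / backward over a whole variant ------------------------------

.as_tensor4 <- function(x3) {
  d <- dim(x3)
  x4 <- array(0, c(d[1], 1L, d[2], d[3]))
  x4[, 1L, , ] <- x3
  x4
}

.stream_fwd <- function(x3, ahat, blocks, keep_cache = TRUE) {
  h <- .as_tensor4(x3)
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    r <- if (blk$type == "temporal") .tb_fwd(h, blk$params, keep_cache)
         else .sp_fwd(h, ahat, blk$params, keep_cache)
    h <- r$out
    if (keep_cache) caches[[b]] <- r$cache
  }
  list(out = h, caches = caches)
}

.stream_bwd <- function(dout, ahat, blocks, caches) {
  grads <- vector("list", length(blocks))
  dh <- dout
  for (b in rev(seq_along(blocks))) {
    blk <- blocks[[b]]
    r <- if (blk$type == "temporal") .tb_bwd(dh, blk$params, caches[[b]])
         else .sp_bwd(dh, ahat, blk$params, caches[[b]])
    dh <- r$dx
    grads[[b]] <- list(params = r$grads)
  }
  grads
}

# flatten (B,C,N,T) to (B*N) x (C*T), node-major rows matching .seq_mat
.flatten_features <- function(h) {
  d <- dim(h)
  m <- aperm(h, c(2, 4, 1, 3))
  dim(m) <- c(d[2] * d[4], d[1] * d[3])
  t(m)
}
.unflatten_features <- function(dm, d) {
  m <- t(dm)
  dim(m) <- c(d[2], d[4], d[1], d[3])
  aperm(m, c(3, 1, 4, 2))
}

# (B,N,T) array to (B*N) x T scalar-sequence matrix
.seq_mat <- function(x3) {
  d <- dim(x3)
  matrix(x3, d[1] * d[2], d[3])
}

.model_forward <- function(model, xa, xc, ahat, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  d <- dim(xa)
  if (length(d) != 3L || d[3] != cfg$window)
    .stopf("input window must be B x N x W with W = %d", cfg$window)
  feats <- list(); caches <- list()
  if (model$variant != "lstm") {
    ra <- .stream_fwd(xa, ahat, p$stream_a, keep_cache)
    rc <- .stream_fwd(xc, ahat, p$stream_c, keep_cache)
    feats$stream_a <- .flatten_features(ra$out)
    feats$stream_c <- .flatten_features(rc$out)
    if (keep_cache) {
      caches$stream_a <- ra$caches; caches$stream_c <- rc$caches
      caches$d_stream <- dim(ra$out)
    }
  }
  if (model$variant != "stgcn2s") {
    rl <- .lstm_fwd(.seq_mat(xa), p$lstm, keep_cache)
    feats$lstm <- rl$out
    if (keep_cache) caches$lstm <- rl$cache
    if (!is.null(p$lstm_c)) {
      rlc <- .lstm_fwd(.seq_mat(xc), p$lstm_c, keep_cache)
      feats$lstm_c <- rlc$out
      if (keep_cache) caches$lstm_c <- rlc$cache
    }
  }
  feat <- do.call(cbind, feats)
  pred_m <- feat %*% t(p$head$W) +
    matrix(p$head$b, nrow(feat), cfg$horizon, byrow = TRUE)
  pred <- array(pred_m, c(d[1], d[2], cfg$horizon))
  list(pred = pred,
       cache = if (keep_cache) list(feat = feat, feats = feats,
                                    caches = caches, d = d))
}

.model_backward <- function(model, dpred, ahat, cache) {
  cfg <- model$config; p <- model$params
  d <- cache$d
  dpred_m <- matrix(dpred, d[1] * d[2], cfg$horizon)
  g <- list()
  g$head <- list(W = crossprod(dpred_m, cache$feat),
                 b = colSums(dpred_m))
  dfeat <- dpred_m %*% p$head$W
  off <- 0L
  take <- function(w) {
    cols <- off + seq_len(w); off <<- off + w
    dfeat[, cols, drop = FALSE]
  }
  if (model$variant != "lstm") {
    sw <- ncol(cache$feats$stream_a)
    da <- .unflatten_features(take(sw), cache$caches$d_stream)
    dc <- .unflatten_features(take(sw), cache$caches$d_stream)
    g$stream_a <- .stream_bwd(da, ahat, p$stream_a, cache$caches$stream_a)
    g$stream_c <- .stream_bwd(dc, ahat, p$stream_c, cache$caches$stream_c)
  }
  if (model$variant != "stgcn2s") {
    g$lstm <- .lstm_bwd(take(cfg$lstm_hidden), p$lstm, cache$caches$lstm)$grads
    if (!is.null(p$lstm_c))
      g$lstm_c <- .lstm_bwd(take(cfg$lstm_hidden), p$lstm_c,
                            cache$caches$lstm_c)$grads
  }
  # reorder to match the params structure
  out <- list()
  for (nm in names(p)) out[[nm]] <- g[[nm]]
  out
}

# --- exported block-level operations (thin wrappers, no caches) -----------

#' Temporal block forward pass
#'
#' Causal convolution along the time axis (left zero padding, kernel tap
#' \eqn{j} reading \eqn{x_{t-j+1}}) followed by a gated linear activation:
#' the pre-activation channels are split into a linear path and a sigmoid
#' gate, multiplied element-wise. \code{activation = "linear"} skips the
#' gate.
#'
#' @param x 4-D array, batch x channels x nodes x time.
#' @param params list with kernel \code{W} (C_pre x C_in x k), bias
#'   \code{b}, and \code{activation} ("glu" or "linear").
#' @return 4-D array batch x C_out x nodes x time.
#' @export
temporal_block_forward <- function(x, params) {
  if (is.null(params$activation)) params$activation <- "glu"
  .tb_fwd(x, params, keep_cache = FALSE)$out
}

#' Spatial block forward pass
#'
#' Aggregates each node's features over its graph neighbours,
#' \eqn{lfs_{b,c,i,t} = \sum_j \hat A_{ij} x_{b,c,j,t}}, then applies a
#' learned channel mix and a ReLU. The graph is the only cross-node
#' information path in the network.
#'
#' @param x 4-D array, batch x channels x nodes x time.
#' @param ahat normalized adjacency, nodes x nodes.
#' @param params list with channel mix \code{M} (C_out x C_in) and bias
#'   \code{b}.
#' @return 4-D array batch x C_out x nodes x time.
#' @export
spatial_block_forward <- function(x, ahat, params) {
  .sp_fwd(x, ahat, params, keep_cache = FALSE)$out
}

#' Recurrent branch forward pass
#'
#' Runs the stacked LSTM (input, forget and output gates plus a memory
#' cell per layer) over each taxon's scalar window and returns the final
#' hidden state per sequence. Hidden entries are bounded in (-1, 1) since
#' the output is a sigmoid gate times a tanh of the cell state.
#'
#' @param x 3-D array, batch x nodes x time (standardized window).
#' @param layers list of per-layer parameter lists (\code{Wx}, \code{Wh},
#'   \code{b}), e.g. from [build_variant()].
#' @return matrix (batch * nodes) x hidden.
#' @export
recurrent_branch_forward <- function(x, layers) {
  .lstm_fwd(.seq_mat(x), layers, keep_cache = FALSE)$out
}

#' Single-stream forward pass
#'
#' Applies the configured temporal-spatial-temporal block stack to one
#' input stream.
#'
#' @param x 3-D array, batch x nodes x time.
#' @param ahat normalized adjacency.
#' @param blocks a stream's block list (e.g. \code{model$params$stream_a}).
#' @return 4-D feature array batch x channels x nodes x time.
#' @export
stream_forward <- function(x, ahat, blocks) {
  .stream_fwd(x, ahat, blocks, keep_cache = FALSE)$out
}

#' Full model forward pass
#'
#' Runs the variant's streams (and recurrent branch), concatenates the
#' per-node features and maps them through the fully connected head to
#' \code{horizon} future standardized abundances per taxon.
#'
#' @param model a [build_variant()] model.
#' @param xa standardized abundance windows, batch x nodes x window.
#' @param xc matching change-stream windows (ignored by the lstm variant).
#' @param ahat normalized adjacency (ignored by the lstm variant).
#' @return array batch x nodes x horizon.
#' @export
microstnet_forward <- function(model, xa, xc = NULL, ahat = NULL) {
  stopifnot(inherits(model, "stnet_model"))
  if (is.null(xc)) {
    xc <- array(0, dim(xa))
    for (n in seq_len(dim(xa)[1]))
      xc[n, , ] <- make_change_stream(array(xa[n, , ], dim(xa)[2:3]))
  }
  if (!identical(dim(xa), dim(xc)))
    .stopf("abundance and change windows must share shape")
  if (is.null(ahat)) ahat <- diag(model$config$n_taxa)
  .model_forward(model, xa, xc, ahat, keep_cache = FALSE)$pred
}
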