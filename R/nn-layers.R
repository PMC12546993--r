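# Neural building blocks with hand-written reverse-mode gradients.
#
# Tensor layout throughout: 4-D arrays dim c(B, C, N, T)
#   B batch (windows), C channels, N nodes (taxa), T time steps.
# Recurrent inputs use 3-D arrays dim c(B, N, T) of standardized scalars.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# channel-major view: C x (B*N*T)
.mat_c <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(2, 1, 3, 4))
  dim(m) <- c(d[2], d[1] * d[3] * d[4])
  m
}
.unmat_c <- function(m, d) {
  dim(m) <- c(nrow(m), d[1], d[3], d[4])
  aperm(m, c(2, 1, 3, 4))
}
# node-major view: N x (B*C*T)
.mat_n <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(3, 1, 2, 4))
  dim(m) <- c(d[3], d[1] * d[2] * d[4])
  m
}
.unmat_n <- function(m, d) {
  dim(m) <- c(nrow(m), d[1], d[2], d[4])
  aperm(m, c(2, 3, 1, 4))
}

# --- temporal block: causal 1-D convolution along time + gated activation ---
# params: W array (C_pre x C_in x k), b length C_pre, activation "glu"
# (C_pre = 2 * C_out, one linear path gated by a sigmoid path) or "linear".
# Left zero padding keeps length T; tap j of the kernel reads x[t - j + 1].

.tb_fwd <- function(x, p, keep_cache = TRUE) {
  d <- dim(x)
  k <- dim(p$W)[3]; c2 <- dim(p$W)[1]; cin <- dim(p$W)[2]
  if (d[2] != cin) .stopf("temporal block: %d input channels, kernel expects %d",
                          d[2], cin)
  M <- d[1] * d[3] * d[4]
  pre_m <- matrix(p$b, c2, M)
  xs_mats <- if (keep_cache) vector("list", k) else NULL
  for (j in seq_len(k)) {
    if (j == 1L) xs <- x
    else {
      xs <- array(0, d)
      xs[, , , j:d[4]] <- x[, , , 1:(d[4] - j + 1L), drop = FALSE]
    }
    m <- .mat_c(xs)
    if (keep_cache) xs_mats[[j]] <- m
    pre_m <- pre_m + matrix(p$W[, , j], c2, cin) %*% m
  }
  pre <- .unmat_c(pre_m, c(d[1], c2, d[3], d[4]))
  if (identical(p$activation, "linear")) {
    return(list(out = pre,
                cache = if (keep_cache) list(xs_mats = xs_mats, d = d)))
  }
  cout <- c2 %/% 2L
  P <- pre[, seq_len(cout), , , drop = FALSE]
  S <- .sigmoid(pre[, cout + seq_len(cout), , , drop = FALSE])
  list(out = P * S,
       cache = if (keep_cache) list(xs_mats = xs_mats, P = P, S = S, d = d))
}

.tb_bwd <- function(dout, p, cache) {
  d <- cache$d
  k <- dim(p$W)[3]; c2 <- dim(p$W)[1]; cin <- dim(p$W)[2]
  if (identical(p$activation, "linear")) {
    dpre <- dout
  } else {
    cout <- c2 %/% 2L
    dpre <- array(0, c(d[1], c2, d[3], d[4]))
    dpre[, seq_len(cout), , ] <- dout * cache$S
    dpre[, cout + seq_len(cout), , ] <-
      dout * cache$P * cache$S * (1 - cache$S)
  }
  dpre_m <- .mat_c(dpre)
  dW <- array(0, dim(p$W))
  dx <- array(0, d)
  for (j in seq_len(k)) {
    dW[, , j] <- dpre_m %*% t(cache$xs_mats[[j]])
    dxs <- .unmat_c(crossprod(matrix(p$W[, , j], c2, cin), dpre_m), d)
    if (j == 1L) dx <- dx + dxs
    else dx[, , , 1:(d[4] - j + 1L)] <-
        dx[, , , 1:(d[4] - j + 1L), drop = FALSE] +
        dxs[, , , j:d[4], drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = rowSums(dpre_m)))
}

# --- spatial block: graph aggregation over nodes + channel mix + ReLU ----
# lfs[b,c,i,t] = sum_j Ahat[i,j] x[b,c,j,t]; then z = M lfs + b, out = relu(z).

.sp_fwd <- function(x, ahat, p, keep_cache = TRUE) {
  d <- dim(x)
  if (nrow(ahat) != d[3]) .stopf("spatial block: adjacency is %d x %d but tensor has %d nodes",
                                 nrow(ahat), ncol(ahat), d[3])
  y <- .unmat_n(ahat %*% .mat_n(x), d)
  ym_c <- .mat_c(y)
  z_m <- p$M %*% ym_c + matrix(p$b, nrow(p$M), ncol(ym_c))
  mask <- z_m > 0
  d_out <- c(d[1], nrow(p$M), d[3], d[4])
  list(out = .unmat_c(z_m * mask, d_out),
       cache = if (keep_cache) list(ym_c = ym_c, mask = mask,
                                    d = d, d_out = d_out))
}

.sp_bwd <- function(dout, ahat, p, cache) {
  dz_m <- .mat_c(dout) * cache$mask
  dy <- .unmat_c(crossprod(p$M, dz_m), cache$d)
  dx <- .unmat_n(crossprod(ahat, .mat_n(dy)), cache$d)
  list(dx = dx,
       grads = list(M = dz_m %*% t(cache$ym_c), b = rowSums(dz_m)))
}

# --- stacked LSTM over scalar sequences ----------------------------------
# x_seq: M x T matrix (M = B*N sequences of scalars). layers: list of
# list(Wx 4H x in, Wh 4H x H, b 4H). Gate row blocks: input, forget,
# cell candidate, output. Returns the last hidden state of the top layer.

.lstm_fwd <- function(x_seq, layers, keep_cache = TRUE) {
  M <- nrow(x_seq); Tn <- ncol(x_seq)
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  inputs <- lapply(seq_len(Tn), function(t) x_seq[, t, drop = FALSE])
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    H <- ncol(p$Wh)
    h <- matrix(0, M, H); cc <- matrix(0, M, H)
    steps <- if (keep_cache) vector("list", Tn) else NULL
    outs <- vector("list", Tn)
    bmat <- matrix(p$b, M, 4L * H, byrow = TRUE)
    for (t in seq_len(Tn)) {
      Z <- inputs[[t]] %*% t(p$Wx) + h %*% t(p$Wh) + bmat
      i <- .sigmoid(Z[, seq_len(H), drop = FALSE])
      f <- .sigmoid(Z[, H + seq_len(H), drop = FALSE])
      g <- tanh(Z[, 2L * H + seq_len(H), drop = FALSE])
      o <- .sigmoid(Z[, 3L * H + seq_len(H), drop = FALSE])
      cn <- f * cc + i * g
      tc <- tanh(cn)
      hn <- o * tc
      if (keep_cache)
        steps[[t]] <- list(x = inputs[[t]], hprev = h, cprev = cc,
                           i = i, f = f, g = g, o = o, tc = tc)
      h <- hn; cc <- cn
      outs[[t]] <- hn
    }
    if (keep_cache) caches[[l]] <- steps
    inputs <- outs
  }
  list(out = inputs[[length(inputs)]],
       cache = if (keep_cache) list(layers = caches, Tn = Tn, M = M))
}

.lstm_bwd <- function(dh_top, layers, cache) {
  Tn <- cache$Tn; M <- cache$M
  L <- length(layers)
  grads <- vector("list", L)
  # dh per time step flowing into the current layer's outputs
  dh_seq <- vector("list", Tn)   # NULL entries mean no gradient at that step
  dh_seq[[Tn]] <- dh_top
  for (l in rev(seq_len(L))) {
    p <- layers[[l]]
    H <- ncol(p$Wh)
    dWx <- array(0, dim(p$Wx)); dWh <- array(0, dim(p$Wh))
    db <- numeric(4L * H)
    dh_next <- matrix(0, M, H); dc_next <- matrix(0, M, H)
    dx_seq <- vector("list", Tn)
    steps <- cache$layers[[l]]
    for (t in rev(seq_len(Tn))) {
      s <- steps[[t]]
      dh <- dh_next
      if (!is.null(dh_seq[[t]])) dh <- dh + dh_seq[[t]]
      do_ <- dh * s$tc
      dc <- dh * s$o * (1 - s$tc^2) + dc_next
      di <- dc * s$g
      df <- dc * s$cprev
      dg <- dc * s$i
      dZ <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      dWx <- dWx + crossprod(dZ, s$x)
      dWh <- dWh + crossprod(dZ, s$hprev)
      db <- db + colSums(dZ)
      dx_seq[[t]] <- dZ %*% p$Wx
      dh_next <- dZ %*% p$Wh
      dc_next <- dc * s$f
    }
    grads[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    dh_seq <- dx_seq  # becomes the output-gradient sequence of layer l - 1
  }
  list(grads = grads, dx_seq = dh_seq)
}
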