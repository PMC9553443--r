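# Reverse-mode autodiff tape.
#
# Nodes are environments holding a value `v` (matrix), an accumulated gradient
# `g` (NULL until backward reaches them) and a backward closure `bw`.  Ops are
# fused at the granularity of whole layers (GRU step, multi-head attention,
# layer norm, 1-D conv) to keep the tape short: training speed in R is bounded
# by per-node overhead, not BLAS.
#
# Layout convention for batched sequences: "time-major stacking".  A batch of B
# sequences padded to length T is a (B*T) x C matrix whose row (t-1)*B + b is
# position t of sequence b.  Padded rows are kept at zero.  Index-0 in any
# gather index means "zero row".

tape_new <- function(train = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$train <- train
  tp$pn <- new.env(parent = emptyenv()) # parameter-name -> leaf node
  tp
}

.emit <- function(tp, v, bw = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$bw <- bw
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

.acc <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

tp_const <- function(tp, v) .emit(tp, as_mat(v))

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1L)
}

tape_backward <- function(tp, loss) {
  loss$g <- matrix(1, nrow(loss$v), ncol(loss$v))
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  invisible(NULL)
}

# ---- elementary ops --------------------------------------------------------

tp_add <- function(tp, a, b) {
  .emit(tp, a$v + b$v, function(g) { .acc(a, g); .acc(b, g) })
}

tp_scale <- function(tp, a, s) {
  .emit(tp, a$v * s, function(g) .acc(a, g * s))
}

# row-wise max as a vector (avoids apply() overhead on wide matrices)
.row_max <- function(S) {
  mx <- S[, 1L]
  nc <- ncol(S)
  if (nc > 1L) for (j in 2L:nc) mx <- pmax(mx, S[, j])
  mx
}

# add a length-C bias to every row of an n x C matrix
.addbias <- function(pre, bv) pre + rep(bv, each = nrow(pre))

# fused dense layer: act(x %*% W + b)
tp_dense <- function(tp, x, W, b = NULL, act = "none") {
  pre <- x$v %*% W$v
  if (!is.null(b)) pre <- .addbias(pre, as.numeric(b$v))
  v <- .act_fwd(pre, act)
  .emit(tp, v, function(g) {
    dpre <- g * .act_bwd(v, act)
    .acc(x, dpre %*% t(W$v))
    .acc(W, crossprod(x$v, dpre))
    if (!is.null(b)) .acc(b, matrix(colSums(dpre), 1L))
  })
}

.act_fwd <- function(x, act) {
  switch(act,
    none = x,
    relu = x * (x > 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    lrelu = { neg <- x < 0; x[neg] <- 0.2 * x[neg]; x },
    stop("unknown activation: ", act)
  )
}

# derivative expressed through the activation *output* v
.act_bwd <- function(v, act) {
  switch(act,
    none = 1,
    relu = (v > 0) * 1,
    tanh = 1 - v * v,
    sigmoid = v * (1 - v),
    lrelu = 0.2 + 0.8 * (v > 0),
    stop("unknown activation: ", act)
  )
}

tp_act <- function(tp, x, act) {
  v <- .act_fwd(x$v, act)
  .emit(tp, v, function(g) .acc(x, g * .act_bwd(v, act)))
}

# multiply each row by a scalar mask entry (recycled down columns)
tp_rowmask <- function(tp, x, mask) {
  m <- as.numeric(mask)
  .emit(tp, x$v * m, function(g) .acc(x, g * m))
}

tp_concat_cols <- function(tp, parts) {
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 1L) return(parts[[1L]])
  widths <- vapply(parts, function(p) ncol(p$v), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  .emit(tp, do.call(cbind, lapply(parts, function(p) p$v)), function(g) {
    for (i in seq_along(parts)) {
      .acc(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

tp_slice_cols <- function(tp, x, cols) {
  nc <- ncol(x$v)
  .emit(tp, x$v[, cols, drop = FALSE], function(g) {
    G <- matrix(0, nrow(x$v), nc)
    G[, cols] <- g
    .acc(x, G)
  })
}

# gather rows; idx == 0 yields a zero row
tp_rows <- function(tp, x, idx) {
  nr <- nrow(x$v)
  idx <- as.integer(idx)
  .emit(tp, cpp_row_gather(x$v, idx), function(g) {
    .acc(x, cpp_row_scatter(g, idx, nr))
  })
}

# linear interpolation across rows: out[i,] = w[i]*x[i1[i],] + (1-w[i])*x[i2[i],]
tp_interp_rows <- function(tp, x, i1, i2, w) {
  nr <- nrow(x$v)
  .emit(tp, cpp_interp_gather(x$v, i1, i2, w), function(g) {
    .acc(x, cpp_interp_scatter(g, i1, i2, w, nr))
  })
}

# repeat an (L x C) block into time-major (B*L) x C
tp_tile_rows <- function(tp, x, B) {
  L <- nrow(x$v)
  idx <- rep(seq_len(L), each = B)
  .emit(tp, x$v[idx, , drop = FALSE], function(g) {
    .acc(x, rowsum(g, group = idx))
  })
}

tp_reshape <- function(tp, x, nr, nc) {
  # row-major reshape: row vector -> (nr x nc) reading across columns first
  v <- matrix(as.numeric(t(x$v)), nr, nc, byrow = TRUE)
  .emit(tp, v, function(g) {
    .acc(x, matrix(as.numeric(t(g)), nrow(x$v), ncol(x$v), byrow = TRUE))
  })
}

tp_dropout <- function(tp, x, p) {
  if (!tp$train || p <= 0) return(x)
  m <- matrix(stats::rbinom(length(x$v), 1L, 1 - p), nrow(x$v)) / (1 - p)
  .emit(tp, x$v * m, function(g) .acc(x, g * m))
}

tp_mean <- function(tp, x) {
  n <- length(x$v)
  .emit(tp, matrix(mean(x$v), 1L, 1L), function(g) {
    .acc(x, matrix(g[1L] / n, nrow(x$v), ncol(x$v)))
  })
}

tp_log <- function(tp, x, eps = 1e-7) {
  xv <- pmin(pmax(x$v, eps), 1 - eps)
  .emit(tp, log(xv), function(g) {
    pass <- (x$v > eps) & (x$v < 1 - eps)
    .acc(x, g / xv * pass)
  })
}

tp_rsub <- function(tp, s, x) { # s - x, s scalar
  .emit(tp, s - x$v, function(g) .acc(x, -g))
}

# ---- layer norm ------------------------------------------------------------

# per-row layer normalisation with affine gain/bias (1 x C parameter nodes)
tp_layernorm <- function(tp, x, gain, bias, eps = 1e-5) {
  ln <- cpp_layernorm_fwd(x$v, eps)
  xn <- ln$xn
  isd <- ln$isd
  gv <- as.numeric(gain$v)
  bv <- as.numeric(bias$v)
  n <- nrow(xn)
  v <- xn * rep(gv, each = n) + rep(bv, each = n)
  .emit(tp, v, function(g) {
    dxn <- g * rep(gv, each = n)
    .acc(x, cpp_layernorm_bwd(dxn, xn, isd))
    .acc(gain, matrix(colSums(g * xn), 1L))
    .acc(bias, matrix(colSums(g), 1L))
  })
}

# ---- GRU step --------------------------------------------------------------

# One fused GRU step over a batch (rows = batch items).  Gate equations (no
# bias terms, matching the model's printed update/reset-gate forms):
#   r = sigmoid(e Wr + p Ur);  z = sigmoid(e Wz + p Uz)
#   pc = tanh(e W + r * (p U));  p' = (1 - z) * p + z * pc
tp_gru_step <- function(tp, e, p, Wr, Ur, Wz, Uz, W, U) {
  up <- p$v %*% U$v
  r <- 1 / (1 + exp(-(e$v %*% Wr$v + p$v %*% Ur$v)))
  z <- 1 / (1 + exp(-(e$v %*% Wz$v + p$v %*% Uz$v)))
  pc <- tanh(e$v %*% W$v + r * up)
  v <- (1 - z) * p$v + z * pc
  .emit(tp, v, function(g) {
    dz <- g * (pc - p$v)
    dpc <- g * z
    dp <- g * (1 - z)
    dac <- dpc * (1 - pc * pc)
    .acc(W, crossprod(e$v, dac))
    de <- dac %*% t(W$v)
    dr <- dac * up
    dup <- dac * r
    .acc(U, crossprod(p$v, dup))
    dp <- dp + dup %*% t(U$v)
    dzp <- dz * z * (1 - z)
    .acc(Wz, crossprod(e$v, dzp))
    .acc(Uz, crossprod(p$v, dzp))
    de <- de + dzp %*% t(Wz$v)
    dp <- dp + dzp %*% t(Uz$v)
    drp <- dr * r * (1 - r)
    .acc(Wr, crossprod(e$v, drp))
    .acc(Ur, crossprod(p$v, drp))
    de <- de + drp %*% t(Wr$v)
    dp <- dp + drp %*% t(Ur$v)
    .acc(e, de)
    .acc(p, dp)
  })
}

# One full GRU layer over a time-major batch, fused into a single node.
# E: (B*T) x d_in; mask: numeric length B*T (1 real / 0 pad); the state is
# re-masked after every step so padding stays zero.  Output is the stacked
# per-step state sequence.
tp_gru_layer <- function(tp, E, mask, B, Tmax, Wr, Ur, Wz, Uz, W, U) {
  dh <- ncol(U$v)
  Ev <- E$v
  state <- matrix(0, B, dh)
  out <- matrix(0, B * Tmax, dh)
  Rc <- Zc <- Pc <- UPc <- PPc <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    e <- Ev[rows, , drop = FALSE]
    up <- state %*% U$v
    r <- 1 / (1 + exp(-(e %*% Wr$v + state %*% Ur$v)))
    z <- 1 / (1 + exp(-(e %*% Wz$v + state %*% Uz$v)))
    pc <- tanh(e %*% W$v + r * up)
    p <- (1 - z) * state + z * pc
    PPc[[t]] <- state
    Rc[[t]] <- r; Zc[[t]] <- z; Pc[[t]] <- pc; UPc[[t]] <- up
    state <- p * mask[rows]
    out[rows, ] <- state
  }
  .emit(tp, out, function(g) {
    dE <- matrix(0, nrow(Ev), ncol(Ev))
    gWr <- matrix(0, nrow(Wr$v), ncol(Wr$v)); gUr <- matrix(0, dh, dh)
    gWz <- gWr; gUz <- gUr; gW <- gWr; gU <- gUr
    carry <- matrix(0, B, dh)
    for (t in seq.int(Tmax, 1L)) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      gp <- (g[rows, , drop = FALSE] + carry) * mask[rows]
      e <- Ev[rows, , drop = FALSE]
      r <- Rc[[t]]; z <- Zc[[t]]; pc <- Pc[[t]]
      up <- UPc[[t]]; pprev <- PPc[[t]]
      dz <- gp * (pc - pprev)
      dpc <- gp * z
      dprev <- gp * (1 - z)
      dac <- dpc * (1 - pc * pc)
      gW <- gW + crossprod(e, dac)
      de <- dac %*% t(W$v)
      dr <- dac * up
      dup <- dac * r
      gU <- gU + crossprod(pprev, dup)
      dprev <- dprev + dup %*% t(U$v)
      dzp <- dz * z * (1 - z)
      gWz <- gWz + crossprod(e, dzp)
      gUz <- gUz + crossprod(pprev, dzp)
      de <- de + dzp %*% t(Wz$v)
      dprev <- dprev + dzp %*% t(Uz$v)
      drp <- dr * r * (1 - r)
      gWr <- gWr + crossprod(e, drp)
      gUr <- gUr + crossprod(pprev, drp)
      de <- de + drp %*% t(Wr$v)
      dprev <- dprev + drp %*% t(Ur$v)
      dE[rows, ] <- de
      carry <- dprev
    }
    .acc(E, dE)
    .acc(Wr, gWr); .acc(Ur, gUr)
    .acc(Wz, gWz); .acc(Uz, gUz)
    .acc(W, gW); .acc(U, gU)
  })
}

# ---- multi-head attention --------------------------------------------------

# Fused multi-head self-attention over a time-major stacked batch.
# E: (B*T) x d_model; lens: per-sequence true lengths.  Returns the
# concatenated-and-projected attention data (the spliced per-head
# fragments).  Padded rows stay zero.
tp_attention <- function(tp, E, Wq, Wk, Wv, Wo, lens, n_heads,
                         rows_b = NULL) {
  B <- length(lens)
  d_model <- ncol(E$v)
  dk <- d_model %/% n_heads
  scl <- 1 / sqrt(dk)
  Q <- E$v %*% Wq$v
  K <- E$v %*% Wk$v
  V <- E$v %*% Wv$v
  if (is.null(rows_b)) {
    rows_b <- lapply(seq_len(B), function(b) {
      b + B * (seq_len(lens[b]) - 1L)
    })
  }
  fw <- cpp_attention_fwd(Q, K, V, rows_b, n_heads, scl)
  Z <- fw$Z
  out <- Z %*% Wo$v
  .emit(tp, out, function(g) {
    dZ <- g %*% t(Wo$v)
    .acc(Wo, crossprod(Z, g))
    bw <- cpp_attention_bwd(dZ, Q, K, V, rows_b, fw$P, n_heads, scl)
    .acc(E, bw$dQ %*% t(Wq$v) + bw$dK %*% t(Wk$v) + bw$dV %*% t(Wv$v))
    .acc(Wq, crossprod(E$v, bw$dQ))
    .acc(Wk, crossprod(E$v, bw$dK))
    .acc(Wv, crossprod(E$v, bw$dV))
  })
}

# ---- 1-D convolution -------------------------------------------------------

# Index matrix for a 1-D conv over a uniform time-major batch: every one of B
# sequences has length L; kernel k, given stride; 'same'-style zero padding.
# Rows of the result are output rows (time-major, length Lout*B); entry j is
# the input row feeding kernel tap j (0 = zero pad).
conv_index <- function(B, L, k, stride = 1L) {
  Lout <- if (stride == 1L) L else ceiling(L / stride)
  pos <- (seq_len(Lout) - 1L) * stride + 1L # leftmost-aligned window starts
  off <- seq_len(k) - (k + 1L) %/% 2L       # centred taps
  idx <- matrix(0L, Lout * B, k)
  for (j in seq_len(k)) {
    tj <- pos + off[j]
    ok <- tj >= 1L & tj <= L
    col <- integer(Lout * B)
    for (b in seq_len(B)) {
      rows <- b + B * (seq_len(Lout) - 1L)
      col[rows] <- ifelse(ok, b + B * (tj - 1L), 0L)
    }
    idx[, j] <- col
  }
  idx
}

# fused conv1d: gathers an im2col matrix by `idx`, multiplies by W
# ((k*Cin) x Cout), adds bias, applies activation.
tp_conv1d <- function(tp, x, W, b, idx, act = "none") {
  nr <- nrow(x$v)
  X2 <- cpp_conv_gather(x$v, idx)
  pre <- X2 %*% W$v
  if (!is.null(b)) pre <- .addbias(pre, as.numeric(b$v))
  v <- .act_fwd(pre, act)
  .emit(tp, v, function(g) {
    dpre <- g * .act_bwd(v, act)
    .acc(W, crossprod(X2, dpre))
    if (!is.null(b)) .acc(b, matrix(colSums(dpre), 1L))
    dX2 <- dpre %*% t(W$v)
    .acc(x, cpp_conv_scatter(dX2, idx, nr))
  })
}

# conv1d followed by layer norm and an activation, in one node
tp_conv_ln_act <- function(tp, x, W, b, gain, bias, idx, act = "relu",
                           eps = 1e-5) {
  nr <- nrow(x$v)
  X2 <- cpp_conv_gather(x$v, idx)
  pre <- X2 %*% W$v
  if (!is.null(b)) pre <- .addbias(pre, as.numeric(b$v))
  ln <- cpp_layernorm_fwd(pre, eps)
  xn <- ln$xn
  gv <- as.numeric(gain$v)
  bv <- as.numeric(bias$v)
  n <- nrow(xn)
  v <- .act_fwd(xn * rep(gv, each = n) + rep(bv, each = n), act)
  .emit(tp, v, function(g) {
    gaff <- g * .act_bwd(v, act)
    dxn <- gaff * rep(gv, each = n)
    .acc(gain, matrix(colSums(gaff * xn), 1L))
    .acc(bias, matrix(colSums(gaff), 1L))
    dpre <- cpp_layernorm_bwd(dxn, xn, ln$isd)
    .acc(W, crossprod(X2, dpre))
    if (!is.null(b)) .acc(b, matrix(colSums(dpre), 1L))
    .acc(x, cpp_conv_scatter(dpre %*% t(W$v), idx, nr))
  })
}

# transposed conv (stride 2, kernel 2) + layer norm + activation, fused
tp_tconv_ln_act <- function(tp, x, W1, W2, b, B, gain, bias, act = "relu",
                            eps = 1e-5) {
  L <- nrow(x$v) %/% B
  y1 <- x$v %*% W1$v
  y2 <- x$v %*% W2$v
  Cout <- ncol(y1)
  pre <- matrix(0, 2L * L * B, Cout)
  odd <- rep(seq_len(B), L) + B * rep(2L * (seq_len(L) - 1L), each = B)
  pre[odd, ] <- y1
  pre[odd + B, ] <- y2
  if (!is.null(b)) pre <- .addbias(pre, as.numeric(b$v))
  ln <- cpp_layernorm_fwd(pre, eps)
  xn <- ln$xn
  gv <- as.numeric(gain$v)
  bv <- as.numeric(bias$v)
  n <- nrow(xn)
  v <- .act_fwd(xn * rep(gv, each = n) + rep(bv, each = n), act)
  .emit(tp, v, function(g) {
    gaff <- g * .act_bwd(v, act)
    dxn <- gaff * rep(gv, each = n)
    .acc(gain, matrix(colSums(gaff * xn), 1L))
    .acc(bias, matrix(colSums(gaff), 1L))
    dpre <- cpp_layernorm_bwd(dxn, xn, ln$isd)
    g1 <- dpre[odd, , drop = FALSE]
    g2 <- dpre[odd + B, , drop = FALSE]
    .acc(W1, crossprod(x$v, g1))
    .acc(W2, crossprod(x$v, g2))
    if (!is.null(b)) .acc(b, matrix(colSums(dpre), 1L))
    .acc(x, g1 %*% t(W1$v) + g2 %*% t(W2$v))
  })
}

# transposed conv, stride 2, kernel 2: interleaves x W1 and x W2 along time.
# x: time-major (B*L) x Cin -> (B*2L) x Cout.
tp_tconv1d <- function(tp, x, W1, W2, b, B) {
  L <- nrow(x$v) %/% B
  y1 <- x$v %*% W1$v
  y2 <- x$v %*% W2$v
  Cout <- ncol(y1)
  v <- matrix(0, 2L * L * B, Cout)
  odd <- rep(b_rows <- seq_len(B), L) + B * rep(2L * (seq_len(L) - 1L), each = B)
  v[odd, ] <- y1
  v[odd + B, ] <- y2
  if (!is.null(b)) v <- .addbias(v, as.numeric(b$v))
  .emit(tp, v, function(g) {
    g1 <- g[odd, , drop = FALSE]
    g2 <- g[odd + B, , drop = FALSE]
    .acc(W1, crossprod(x$v, g1))
    .acc(W2, crossprod(x$v, g2))
    if (!is.null(b)) .acc(b, matrix(colSums(g), 1L))
    .acc(x, g1 %*% t(W1$v) + g2 %*% t(W2$v))
  })
}

# ---- pooling ---------------------------------------------------------------

# global max pool over valid time rows of each sequence -> B x C
tp_maxpool_time <- function(tp, x, B, lens) {
  C <- ncol(x$v)
  v <- matrix(0, B, C)
  arg <- matrix(0L, B, C)
  for (b in seq_len(B)) {
    Tb <- lens[b]
    if (Tb == 0L) next
    rb <- b + B * (seq_len(Tb) - 1L)
    xb <- x$v[rb, , drop = FALSE]
    am <- max.col(t(xb), ties.method = "first")
    v[b, ] <- xb[cbind(am, seq_len(C))]
    arg[b, ] <- rb[am]
  }
  .emit(tp, v, function(g) {
    G <- matrix(0, nrow(x$v), C)
    for (b in seq_len(B)) {
      if (lens[b] == 0L) next
      G[cbind(arg[b, ], seq_len(C))] <- G[cbind(arg[b, ], seq_len(C))] + g[b, ]
    }
    .acc(x, G)
  })
}

# mean pool over valid time rows of each sequence -> B x C
tp_meanpool_time <- function(tp, x, B, lens) {
  sid <- rep(seq_len(B), nrow(x$v) %/% B)
  rs <- rowsum(x$v, group = sid)
  v <- rs / pmax(lens, 1L)
  .emit(tp, v, function(g) {
    .acc(x, (g / pmax(lens, 1L))[sid, , drop = FALSE])
  })
}

# ---- losses ----------------------------------------------------------------

# mean softmax cross-entropy over valid rows; gold is a 1-based class id per
# row (0 = ignore/padded row)
tp_ce <- function(tp, scores, gold) {
  keep <- gold > 0L
  n <- sum(keep)
  P <- cpp_softmax_rows(scores$v)
  pick <- P[cbind(seq_len(nrow(P)), pmax(gold, 1L))]
  v <- -sum(log(pmax(pick[keep], 1e-12))) / max(n, 1L)
  .emit(tp, matrix(v, 1L, 1L), function(g) {
    G <- P
    G[cbind(seq_len(nrow(P)), pmax(gold, 1L))] <-
      G[cbind(seq_len(nrow(P)), pmax(gold, 1L))] - 1
    G[!keep, ] <- 0
    .acc(scores, G * (g[1L] / max(n, 1L)))
  })
}

tp_softmax_rows <- function(tp, x) {
  P <- cpp_softmax_rows(x$v)
  .emit(tp, P, function(g) {
    .acc(x, P * (g - rowSums(g * P)))
  })
}
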