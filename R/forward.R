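# Tape forward passes: multigranularity encoders, the conditioned U-shaped
# generator, and the convolutional discriminator.  All functions take a tape
# `tp`, a parameter store `ps` (generator) or `psd` (discriminator), a batch
# structure from make_batches(), and the configuration.

.emb_lookup <- function(tp, ps, name, ids, vocab_size, d, cfg) {
  E <- P(tp, ps, name, vocab_size, d, init = "normal", sd = 0.1)
  x <- tp_rows(tp, E, ids + 1L) # 0-based ids; id 0 (<pad>) row is learned
  tp_dropout(tp, x, cfg$dropout)
}

.sinusoidal_pe <- function(Tmax, d) {
  pos <- seq_len(Tmax)
  pe <- matrix(0, Tmax, d)
  for (j in seq_len(d %/% 2L)) {
    ang <- pos / 10000^(2 * (j - 1) / d)
    pe[, 2L * j - 1L] <- sin(ang)
    pe[, 2L * j] <- cos(ang)
  }
  pe
}

# add sinusoidal positional encoding in time-major layout (if enabled)
.add_pe <- function(tp, x, B, Tmax, cfg) {
  if (cfg$positional_encoding != "sinusoidal") return(x)
  pe <- .sinusoidal_pe(Tmax, ncol(x$v))
  tp_add(tp, x, tp_const(tp, pe[rep(seq_len(Tmax), each = B), ]))
}

# ---- character-granularity encoder (two GRU layers + FC tanh) -------------

cgfe_forward <- function(tp, ps, bt, cfg, vocab_size) {
  d <- cfg$d_model
  dh <- cfg$gru_hidden
  emb <- if (cfg$share_embeddings) "emb_shared" else "emb_c"
  E <- .emb_lookup(tp, ps, emb, bt$ids, vocab_size, d, cfg)
  B <- bt$B
  h <- E
  for (layer in 1:2) {
    pre <- paste0("cg", layer, "_")
    din <- if (layer == 1L) d else dh
    Wr <- P(tp, ps, paste0(pre, "Wr"), din, dh)
    Ur <- P(tp, ps, paste0(pre, "Ur"), dh, dh)
    Wz <- P(tp, ps, paste0(pre, "Wz"), din, dh)
    Uz <- P(tp, ps, paste0(pre, "Uz"), dh, dh)
    W <- P(tp, ps, paste0(pre, "W"), din, dh)
    U <- P(tp, ps, paste0(pre, "U"), dh, dh)
    h <- tp_gru_layer(tp, h, bt$mask, B, bt$Tmax, Wr, Ur, Wz, Uz, W, U)
  }
  fcW <- P(tp, ps, "cg_fc_W", dh, dh)
  fcb <- P(tp, ps, "cg_fc_b", 1L, dh, init = "zeros")
  hc <- tp_dense(tp, h, fcW, fcb, act = "tanh")
  tp_rowmask(tp, hc, bt$mask)
}

# ---- Transformer encoder stack (sentence / paragraph granularity) ---------

# returns list(a = layer-6 attention data, h = layer-6 contextual output)
transformer_forward <- function(tp, ps, prefix, ids, lens, B, mask, cfg,
                                vocab_size, rows_b = NULL) {
  d <- cfg$d_model
  emb <- if (cfg$share_embeddings) "emb_shared" else paste0("emb_", prefix)
  E <- .emb_lookup(tp, ps, emb, ids, vocab_size, d, cfg)
  E <- .add_pe(tp, E, B, length(ids) %/% B, cfg)
  E <- tp_rowmask(tp, E, mask)
  f <- E
  a <- NULL
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0(prefix, l, "_")
    Wq <- P(tp, ps, paste0(pre, "Wq"), d, d)
    Wk <- P(tp, ps, paste0(pre, "Wk"), d, d)
    Wv <- P(tp, ps, paste0(pre, "Wv"), d, d)
    Wo <- P(tp, ps, paste0(pre, "Wo"), d, d)
    a <- tp_attention(tp, f, Wq, Wk, Wv, Wo, lens, cfg$n_heads, rows_b)
    g1 <- P(tp, ps, paste0(pre, "g1"), 1L, d, init = "ones")
    c1 <- P(tp, ps, paste0(pre, "c1"), 1L, d, init = "zeros")
    g2 <- P(tp, ps, paste0(pre, "g2"), 1L, d, init = "ones")
    c2 <- P(tp, ps, paste0(pre, "c2"), 1L, d, init = "zeros")
    W1 <- P(tp, ps, paste0(pre, "W1"), d, d)
    b1 <- P(tp, ps, paste0(pre, "b1"), 1L, d, init = "zeros")
    x <- tp_add(tp, a, f)
    x1 <- tp_layernorm(tp, x, g1, c1)
    if (cfg$encoder_block == "paper") {
      ff <- tp_dense(tp, x1, W1, b1)
      h <- tp_layernorm(tp, tp_add(tp, x1, ff), g2, c2)
    } else {
      W2 <- P(tp, ps, paste0(pre, "W2"), d, d)
      b2 <- P(tp, ps, paste0(pre, "b2"), 1L, d, init = "zeros")
      hid <- tp_dense(tp, x1, W1, b1, act = "relu")
      ff <- tp_dense(tp, hid, W2, b2)
      h <- tp_layernorm(tp, tp_add(tp, x1, ff), g2, c2)
    }
    h <- tp_dropout(tp, h, cfg$dropout)
    h <- tp_rowmask(tp, h, mask)
    f <- h
  }
  list(a = tp_rowmask(tp, a, mask), h = f)
}

# ---- chapter-granularity encoder (3 conv layers, max pool, FC) ------------

agfe_forward <- function(tp, ps, bt, cfg, vocab_size) {
  d <- cfg$d_model
  C <- cfg$article_dim
  emb <- if (cfg$share_embeddings) "emb_shared" else "emb_a"
  E <- .emb_lookup(tp, ps, emb, bt$ids_c, vocab_size, d, cfg)
  x <- E
  cin <- d
  for (l in 1:3) {
    W <- P(tp, ps, paste0("ag_conv", l, "_W"), 3L * cin, C)
    b <- P(tp, ps, paste0("ag_conv", l, "_b"), 1L, C, init = "zeros")
    x <- tp_conv1d(tp, x, W, b, bt$conv_idx_chap, act = "relu")
    cin <- C
  }
  pooled <- tp_maxpool_time(tp, x, bt$Bc, bt$clen)
  W <- P(tp, ps, "ag_fc_W", C, C)
  b <- P(tp, ps, "ag_fc_b", 1L, C, init = "zeros")
  h <- tp_dense(tp, tp_dropout(tp, pooled, cfg$dropout), W, b, act = "relu")
  h # Bc x article_dim
}

# ---- label seed feature encoder (6 stride-2 conv levels) ------------------

lsfe_forward <- function(tp, ps, seed_vec, cfg) {
  L0 <- cfg$seed_len
  c0 <- cfg$seed_c0
  s <- tp_const(tp, matrix(as.numeric(seed_vec), 1L))
  # factorised projection keeps the parameter count modest
  Wa <- P(tp, ps, "ls_proj_Wa", length(seed_vec), 64L)
  ba <- P(tp, ps, "ls_proj_ba", 1L, 64L, init = "zeros")
  Wp <- P(tp, ps, "ls_proj_W", 64L, L0 * c0)
  bp <- P(tp, ps, "ls_proj_b", 1L, L0 * c0, init = "zeros")
  x <- tp_reshape(tp, tp_dense(tp, tp_dense(tp, s, Wa, ba, act = "tanh"),
                               Wp, bp), L0, c0)
  proj <- x
  skips <- vector("list", 6L)
  cin <- c0
  L <- L0
  for (l in 1:6) {
    Cout <- cfg$enc_channels[l]
    idx <- conv_index(1L, L, 3L, stride = 2L)
    W <- P(tp, ps, paste0("ls_conv", l, "_W"), 3L * cin, Cout)
    b <- P(tp, ps, paste0("ls_conv", l, "_b"), 1L, Cout, init = "zeros")
    g <- P(tp, ps, paste0("ls_ln", l, "_g"), 1L, Cout, init = "ones")
    cc <- P(tp, ps, paste0("ls_ln", l, "_c"), 1L, Cout, init = "zeros")
    x <- tp_conv_ln_act(tp, x, W, b, g, cc, idx,
                        act = if (l < 6L) "relu" else "tanh")
    skips[[l]] <- x
    cin <- Cout
    L <- L %/% 2L
  }
  list(skips = skips, bottom = skips[[6L]], proj = proj)
}

# ---- full generator -------------------------------------------------------

generator_forward <- function(tp, ps, bt, cfg, seed_vec, vocab_size, n_tags,
                              want_attention = FALSE) {
  gr <- cfg$granularities
  h_c <- if ("char" %in% gr) cgfe_forward(tp, ps, bt, cfg, vocab_size)
  sg <- if ("sentence" %in% gr) {
    transformer_forward(tp, ps, "s", bt$ids, bt$lens, bt$B, bt$mask, cfg,
                        vocab_size, bt$rows_s)
  }
  pg_raw <- if ("paragraph" %in% gr) {
    transformer_forward(tp, ps, "p", bt$ids_p, bt$plen, bt$P, bt$mask_p,
                        cfg, vocab_size, bt$rows_p)
  }
  # re-split paragraph-granularity outputs to sentence positions
  a_p <- h_p <- NULL
  if (!is.null(pg_raw)) {
    a_p <- tp_rows(tp, pg_raw$a, bt$map_sp)
    h_p <- tp_rows(tp, pg_raw$h, bt$map_sp)
  }
  h_a_rows <- NULL
  if ("chapter" %in% gr) {
    ha <- agfe_forward(tp, ps, bt, cfg, vocab_size)
    h_a_rows <- tp_rows(tp, ha, bt$chap_row)
  }

  # main input A: spliced attention data (or white noise ablation)
  att_parts <- list()
  if (!is.null(sg)) att_parts <- c(att_parts, list(sg$a))
  if (!is.null(a_p)) att_parts <- c(att_parts, list(a_p))
  A_raw <- tp_concat_cols(tp, att_parts)
  if (cfg$main_input == "noise") {
    A_raw <- tp_const(tp, matrix(stats::rnorm(length(A_raw$v)),
                                 nrow(A_raw$v)) * bt$mask)
  }
  WA <- P(tp, ps, "main_W", ncol(A_raw$v), cfg$d_main)
  bA <- P(tp, ps, "main_b", 1L, cfg$d_main, init = "zeros")
  A <- tp_dense(tp, A_raw, WA, bA)
  A <- tp_rowmask(tp, A, bt$mask)

  ls <- lsfe_forward(tp, ps, seed_vec, cfg)

  # condition Y: splice multigranularity features with the encoded seed
  # bottom ("+" joins the same-width sentence and paragraph contexts)
  C6 <- cfg$enc_channels[6L]
  Lb <- cfg$seed_len %/% 64L # bottom pseudo-sequence length
  bot_flat <- tp_reshape(tp, ls$bottom, 1L, Lb * C6)
  Wb <- P(tp, ps, "bot_W", Lb * C6, cfg$d_cond)
  bb <- P(tp, ps, "bot_b", 1L, cfg$d_cond, init = "zeros")
  bot_proj <- tp_dense(tp, bot_flat, Wb, bb)
  bot_rows <- tp_rows(tp, bot_proj, as.integer(bt$mask > 0))
  if (cfg$condition == "Y") {
    hsp <- if (!is.null(sg) && !is.null(h_p)) tp_add(tp, sg$h, h_p)
    else if (!is.null(sg)) sg$h else h_p
    y_parts <- list(h_c, hsp, h_a_rows, bot_rows)
    Ypre <- tp_concat_cols(tp, y_parts)
  } else { # condition = L: gold labels during training, zeros at prediction
    lab <- matrix(0, bt$B * bt$Tmax, n_tags)
    if (tp$train) {
      valid <- bt$gold > 0L
      lab[cbind(which(valid), bt$gold[valid])] <- 1
    }
    Ypre <- tp_concat_cols(tp, list(tp_const(tp, lab), bot_rows))
  }
  Wy <- P(tp, ps, "cond_W", ncol(Ypre$v), cfg$d_cond)
  by <- P(tp, ps, "cond_b", 1L, cfg$d_cond, init = "zeros")
  Y <- tp_dense(tp, Ypre, Wy, by)
  Y <- tp_rowmask(tp, Y, bt$mask)

  # FALG decoder: six up-sampling levels; at each level the matching
  # seed-encoder skip is spliced in together with the per-position main
  # input and condition, resampled to the level's length
  B <- bt$B
  state <- tp_tile_rows(tp, ls$bottom, B)
  cin <- C6
  for (l in 1:6) {
    Cout <- cfg$dec_channels[l]
    W1 <- P(tp, ps, paste0("de", l, "_tc1"), cin, Cout)
    W2 <- P(tp, ps, paste0("de", l, "_tc2"), cin, Cout)
    tb <- P(tp, ps, paste0("de", l, "_tcb"), 1L, Cout, init = "zeros")
    g1 <- P(tp, ps, paste0("de", l, "_g1"), 1L, Cout, init = "ones")
    c1 <- P(tp, ps, paste0("de", l, "_c1"), 1L, Cout, init = "zeros")
    state <- tp_tconv_ln_act(tp, state, W1, W2, tb, B, g1, c1,
                             act = "relu")
    skip <- if (l < 6L) tp_tile_rows(tp, ls$skips[[6L - l]], B)
    else tp_tile_rows(tp, ls$proj, B)
    ii <- bt$interp[[l]]
    A_l <- tp_interp_rows(tp, A, ii$i1, ii$i2, ii$w)
    Y_l <- tp_interp_rows(tp, Y, ii$i1, ii$i2, ii$w)
    state <- tp_concat_cols(tp, list(state, skip, A_l, Y_l))
    cin <- Cout + ncol(skip$v) + cfg$d_main + cfg$d_cond
    if (l > 1L) {
      Wc <- P(tp, ps, paste0("de", l, "_cv"), 3L * cin, Cout)
      bc <- P(tp, ps, paste0("de", l, "_cb"), 1L, Cout, init = "zeros")
      if (l < 6L) {
        g2 <- P(tp, ps, paste0("de", l, "_g2"), 1L, Cout, init = "ones")
        c2 <- P(tp, ps, paste0("de", l, "_c2"), 1L, Cout, init = "zeros")
        state <- tp_conv_ln_act(tp, state, Wc, bc, g2, c2,
                                bt$conv_idx[[l]], act = "relu")
      } else {
        state <- tp_conv1d(tp, state, Wc, bc, bt$conv_idx[[l]],
                           act = "tanh")
      }
      cin <- Cout
    }
  }

  # resample the decoded feature sequence back to the exact text length
  bk <- bt$back
  top <- tp_interp_rows(tp, state, bk$i1, bk$i2, bk$w)
  Wh <- P(tp, ps, "head_W", cin, n_tags)
  bh <- P(tp, ps, "head_b", 1L, n_tags, init = "zeros")
  scores <- tp_dense(tp, top, Wh, bh)
  scores <- tp_rowmask(tp, scores, bt$mask)
  out <- list(scores = scores)
  if (want_attention) {
    out$a_s <- if (!is.null(sg)) sg$a
    out$a_p <- a_p
    out$h_c <- h_c
  }
  out
}

# ---- discriminator --------------------------------------------------------

# label_node: (B*T) x n_tags score-vector sequence (softmaxed generator
# output or one-hot gold); cond: one-hot gold labels as the conditional
# input.  7 conv layers with layer norm + LeakyReLU, mean-pool, sigmoid.
discriminator_forward <- function(tp, psd, label_node, cond_mat, bt, cfg) {
  x <- tp_concat_cols(tp, list(label_node, tp_const(tp, cond_mat)))
  cin <- ncol(x$v)
  for (l in 1:7) {
    Cout <- cfg$disc_channels[l]
    W <- P(tp, psd, paste0("di", l, "_W"), 3L * cin, Cout)
    b <- P(tp, psd, paste0("di", l, "_b"), 1L, Cout, init = "zeros")
    g <- P(tp, psd, paste0("di", l, "_g"), 1L, Cout, init = "ones")
    cc <- P(tp, psd, paste0("di", l, "_c"), 1L, Cout, init = "zeros")
    x <- tp_conv_ln_act(tp, x, W, b, g, cc, bt$conv_idx_sent,
                        act = "lrelu")
    x <- tp_rowmask(tp, x, bt$mask)
    cin <- Cout
  }
  pooled <- tp_meanpool_time(tp, x, bt$B, bt$lens)
  W <- P(tp, psd, "di_fc_W", cin, 1L)
  b <- P(tp, psd, "di_fc_b", 1L, 1L, init = "zeros")
  tp_dense(tp, pooled, W, b, act = "sigmoid") # B x 1 scores in (0,1)
}
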