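# Independent brute-force oracles, deliberately coded with explicit scalar
# loops so they share nothing with the package's vectorised/compiled paths.

# gated-recurrence step, one component at a time
oracle_gru <- function(e, p_prev, params) {
  dh <- length(p_prev)
  sig <- function(x) 1 / (1 + exp(-x))
  lin <- function(M, x) { # x %*% M, scalar loops
    out <- numeric(ncol(M))
    for (j in seq_len(ncol(M))) {
      s <- 0
      for (i in seq_len(nrow(M))) s <- s + x[i] * M[i, j]
      out[j] <- s
    }
    out
  }
  r <- sig(lin(params$Wr, e) + lin(params$Ur, p_prev))
  z <- sig(lin(params$Wz, e) + lin(params$Uz, p_prev))
  pc <- tanh(lin(params$W, e) + r * lin(params$U, p_prev))
  (1 - z) * p_prev + z * pc
}

# softmax(Q K^T / sqrt(dk)) V with explicit loops
oracle_attention <- function(Q, K, V) {
  n <- nrow(Q); dk <- ncol(Q)
  Z <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (c in seq_len(ncol(V))) Z[i, c] <- sum(w * V[, c])
  }
  Z
}

oracle_multihead <- function(E, params, n_heads = 8L) {
  d <- ncol(E); dk <- d %/% n_heads
  Q <- E %*% params$Wq; K <- E %*% params$Wk; V <- E %*% params$Wv
  Z <- matrix(0, nrow(E), d)
  for (h in seq_len(n_heads)) {
    ch <- ((h - 1L) * dk + 1L):(h * dk)
    Z[, ch] <- oracle_attention(Q[, ch, drop = FALSE],
                                K[, ch, drop = FALSE],
                                V[, ch, drop = FALSE])
  }
  Z %*% params$Wo
}

oracle_layernorm <- function(x, g = NULL, b = NULL, eps = 1e-5) {
  if (is.null(g)) g <- rep(1, ncol(x))
  if (is.null(b)) b <- rep(0, ncol(x))
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    va <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(va + eps) * g + b
  }
  out
}

# as-printed encoder block: LN(LN(a+f) + Linear(LN(a+f)))
oracle_encoder_layer <- function(a, f, params) {
  x1 <- oracle_layernorm(a + f, params$g1, params$c1)
  ff <- x1 %*% params$W1
  for (i in seq_len(nrow(ff))) ff[i, ] <- ff[i, ] + params$b1
  oracle_layernorm(x1 + ff, params$g2, params$c2)
}

# exhaustive Viterbi: enumerate every path, first-index tie-break
oracle_viterbi <- function(em, trans, start, stop) {
  Tn <- nrow(em); n <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn),
                                 KEEP.OUT.ATTRS = FALSE))
  # the DP resolves ties lowest-index-first while backtracking from the
  # final position, i.e. it returns the minimum of the optimal paths under
  # (p_T, p_{T-1}, ..., p_1) ordering; enumerate in that order and keep the
  # first strict maximum
  ord <- do.call(order, as.data.frame(paths[, Tn:1, drop = FALSE]))
  paths <- paths[ord, , drop = FALSE]
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    s <- start[p[1]] + em[1, p[1]] + stop[p[Tn]]
    if (Tn > 1) {
      for (t in 2:Tn) s <- s + trans[p[t - 1], p[t]] + em[t, p[t]]
    }
    if (s > best) { best <- s; best_path <- p }
  }
  unname(best_path)
}

# span-set evaluation oracle: intersection of (sentence, start, end, type)
oracle_prf <- function(pred_tags, gold_tags) {
  spans <- function(tags, sid) {
    out <- character(0)
    i <- 1L
    while (i <= length(tags)) {
      tg <- tags[i]
      if (tg != "O") {
        code <- substring(tg, 3L)
        j <- i + 1L
        while (j <= length(tags) && tags[j] == paste0("I-", code)) {
          j <- j + 1L
        }
        out <- c(out, paste(sid, i - 1L, j - 1L, code, sep = "|"))
        i <- j
      } else i <- i + 1L
    }
    out
  }
  pk <- unlist(lapply(seq_along(pred_tags),
                      function(s) spans(pred_tags[[s]], s)))
  gk <- unlist(lapply(seq_along(gold_tags),
                      function(s) spans(gold_tags[[s]], s)))
  tp <- length(intersect(pk, gk))
  p <- if (length(pk)) tp / length(pk) else 0
  r <- if (length(gk)) tp / length(gk) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = 100 * p, R = 100 * r, F1 = 100 * f)
}

rand_mat <- function(n, m, sd = 1) matrix(rnorm(n * m, 0, sd), n, m)
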