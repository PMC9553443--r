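# Multigranularity text feature encoder primitives, exposed as plain-matrix
# functions.  These are the reference forms of the operations the training
# tape implements with fused gradient closures; they share no code with the
# test oracles.

#' One GRU step of the character-position encoder
#'
#' Computes a single recurrence step of the gated unit used by the
#' character-granularity feature encoder.  With input vector \eqn{e_i} and
#' previous relative-position state \eqn{p_{i-1}}:
#' \deqn{r_i = \sigma(W^{(r)} e_i + U^{(r)} p_{i-1})}
#' \deqn{z_i = \sigma(W^{(z)} e_i + U^{(z)} p_{i-1})}
#' \deqn{p_i' = \tanh(W e_i + r_i \odot U p_{i-1})}
#' \deqn{p_i = (1 - z_i) \odot p_{i-1} + z_i \odot p_i'}
#' The reset gate \eqn{r_i} controls how much of the previous position
#' information enters the candidate state; the update gate \eqn{z_i} mixes the
#' previous state with the candidate.  No bias terms are used.
#'
#' @param e input vector (length \code{d_in}).
#' @param p_prev previous state vector (length \code{d_h}).
#' @param params list with matrices \code{Wr}, \code{Ur}, \code{Wz},
#'   \code{Uz}, \code{W}, \code{U}; the \code{W*} act on \code{e}
#'   (\code{d_in x d_h}), the \code{U*} on \code{p_prev} (\code{d_h x d_h}).
#' @param clamp_z optional numeric in \code{[0, 1]}; if given, the update
#'   gate is clamped to this constant (used to probe the identity and
#'   full-update limits).
#' @return list with \code{p} (new state), \code{r}, \code{z}, \code{p_cand}.
#' @export
gru_step <- function(e, p_prev, params, clamp_z = NULL) {
  e <- as.numeric(e)
  p_prev <- as.numeric(p_prev)
  er <- e %*% params$Wr
  ez <- e %*% params$Wz
  ew <- e %*% params$W
  if (ncol(params$Ur) != length(p_prev)) stop("state dimension mismatch")
  r <- as.numeric(1 / (1 + exp(-(er + p_prev %*% params$Ur))))
  z <- as.numeric(1 / (1 + exp(-(ez + p_prev %*% params$Uz))))
  if (!is.null(clamp_z)) z <- rep(clamp_z, length(z))
  pc <- as.numeric(tanh(ew + r * (p_prev %*% params$U)))
  p <- (1 - z) * p_prev + z * pc
  list(p = p, r = r, z = z, p_cand = pc)
}

#' Scaled dot-product attention for one head
#'
#' \deqn{Z_h = \mathrm{softmax}(Q_h K_h^\top / \sqrt{d_k}) V_h}
#' Masked (padding) positions receive zero attention weight and contribute
#' zero output; every attention-weight row sums to one over the unmasked
#' positions.
#'
#' @param Q,K,V matrices with one row per position; \code{Q} and \code{K}
#'   share \code{d_k} columns.
#' @param mask logical vector, \code{TRUE} for real positions.  Default all
#'   positions unmasked.
#' @return list with \code{Z} (same rows as \code{V}) and the attention
#'   weight matrix \code{weights}.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  n <- nrow(Q)
  if (nrow(K) != n || nrow(V) != n) stop("Q, K, V row counts differ")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!any(mask)) stop("all positions masked: degenerate softmax")
  dk <- ncol(Q)
  S <- Q %*% t(K) / sqrt(dk)
  S[, !mask] <- -Inf
  S <- S - apply(S, 1L, max)
  W <- exp(S)
  W <- W / rowSums(W)
  W[!mask, ] <- 0
  Z <- W %*% V
  list(Z = Z, weights = W)
}

#' Multi-head self-attention (attention data)
#'
#' Projects the input sequence through per-head query/key/value matrices,
#' applies scaled dot-product attention per head, splices the eight fragments
#' and projects with the output matrix:
#' \eqn{a = \mathrm{concat}(Z_1, \ldots, Z_H) W_O}.
#'
#' @param E input matrix, one row per position (\code{n x d_model}).
#' @param params list with \code{Wq}, \code{Wk}, \code{Wv}, \code{Wo}
#'   (\code{d_model x d_model} each; head \code{h} owns the \code{h}-th
#'   column block of width \code{d_model / n_heads}).
#' @param mask logical vector as in [scaled_dot_attention()].
#' @param n_heads number of parallel attention heads (default 8).
#' @return matrix of attention data, same shape as \code{E}.
#' @export
multihead <- function(E, params, mask = NULL, n_heads = 8L) {
  d <- ncol(E)
  if (d %% n_heads != 0L) stop("d_model not divisible by n_heads")
  dk <- d %/% n_heads
  Q <- E %*% params$Wq
  K <- E %*% params$Wk
  V <- E %*% params$Wv
  Z <- matrix(0, nrow(E), d)
  for (h in seq_len(n_heads)) {
    ch <- ((h - 1L) * dk + 1L):(h * dk)
    Z[, ch] <- scaled_dot_attention(Q[, ch, drop = FALSE],
                                    K[, ch, drop = FALSE],
                                    V[, ch, drop = FALSE], mask)$Z
  }
  Z %*% params$Wo
}

#' Layer normalisation of each row
#'
#' @param x matrix; each row is normalised to zero mean and unit variance
#'   (population variance, epsilon-stabilised), then scaled and shifted.
#' @param gain,bias per-column affine parameters (default identity).
#' @param eps numerical stabiliser.
#' @export
layer_norm <- function(x, gain = NULL, bias = NULL, eps = 1e-5) {
  if (is.null(gain)) gain <- rep(1, ncol(x))
  if (is.null(bias)) bias <- rep(0, ncol(x))
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  xn <- xc / sqrt(va + eps)
  sweep(sweep(xn, 2L, gain, "*"), 2L, bias, "+")
}

#' One Transformer encoding layer, as-printed block form
#'
#' The contextual output of encoding layer \eqn{i} is computed from its
#' attention data \eqn{a_i} and the previous layer's output \eqn{f} as
#' \deqn{h_i = \mathrm{LayerNorm}(\mathrm{LayerNorm}(a_i + f) +
#'       \mathrm{Linear}(\mathrm{LayerNorm}(a_i + f)))}
#' This normalises the residual sum before the feed-forward map and again
#' after its residual, which differs from the canonical Transformer block;
#' the canonical form is available via \code{block = "canonical"} (inner
#' normalisation, two-layer ReLU feed-forward, outer residual).
#'
#' @param a attention data matrix for this layer.
#' @param f previous layer output (or the embedded input for layer 1).
#' @param params list with \code{W1}, \code{b1} (and for the canonical block
#'   \code{W2}, \code{b2}), plus layer-norm affines \code{g1}, \code{c1},
#'   \code{g2}, \code{c2}.
#' @param block \code{"paper"} (default) or \code{"canonical"}.
#' @export
encoder_layer <- function(a, f, params, block = c("paper", "canonical")) {
  block <- match.arg(block)
  x <- a + f
  x1 <- layer_norm(x, params$g1, params$c1)
  if (block == "paper") {
    ff <- sweep(x1 %*% params$W1, 2L, params$b1, "+")
    layer_norm(x1 + ff, params$g2, params$c2)
  } else {
    hid <- pmax(sweep(x1 %*% params$W1, 2L, params$b1, "+"), 0)
    ff <- sweep(hid %*% params$W2, 2L, params$b2, "+")
    layer_norm(x1 + ff, params$g2, params$c2)
  }
}

#' Splice sentence- and paragraph-granularity attention data
#'
#' Per-position concatenation of the two attention streams, sentence first;
#' the result is the generator's main input, taking the place of the white
#' noise a plain conditional GAN would use.
#'
#' @param a_s,a_p per-position attention matrices of equal row count.
#' @return matrix with \code{ncol(a_s) + ncol(a_p)} columns.
#' @export
fuse_attention <- function(a_s, a_p) {
  if (nrow(a_s) != nrow(a_p)) stop("attention sequence lengths differ")
  cbind(a_s, a_p)
}
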