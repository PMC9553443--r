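# Differentiation engine: finite-difference checks of the fused operations
# and the convolution index arithmetic.

fd_check <- function(build, param_mat, eps = 1e-5, tol = 1e-4) {
  # build(mat) must return the scalar loss node and, on the side, keep the
  # tape so gradients can be read; returns max relative error over a few
  # random coordinates
  r <- build(param_mat)
  nergan:::tape_backward(r$tape, r$loss)
  g <- r$node$g
  worst <- 0
  set.seed(99)
  for (k in 1:6) {
    i <- sample(length(param_mat), 1)
    m1 <- param_mat; m1[i] <- m1[i] + eps
    m2 <- param_mat; m2[i] <- m2[i] - eps
    fd <- (build(m1)$loss$v[1] - build(m2)$loss$v[1]) / (2 * eps)
    rel <- abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i]))
    worst <- max(worst, rel)
  }
  worst
}

test_that("gru step gradients match finite differences", {
  set.seed(1)
  B <- 3L; d <- 4L
  e <- rand_mat(B, d); p0 <- rand_mat(B, d)
  mats <- replicate(6, rand_mat(d, d, 0.5), simplify = FALSE)
  names(mats) <- c("Wr", "Ur", "Wz", "Uz", "W", "U")
  for (target in c("Wr", "U", "W")) {
    worst <- fd_check(function(m) {
      mm <- mats; mm[[target]] <- m
      tp <- nergan:::tape_new()
      nd <- lapply(mm, function(x) nergan:::tp_const(tp, x))
      en <- nergan:::tp_const(tp, e)
      pn <- nergan:::tp_const(tp, p0)
      out <- nergan:::tp_gru_step(tp, en, pn, nd$Wr, nd$Ur, nd$Wz, nd$Uz,
                                  nd$W, nd$U)
      list(tape = tp, loss = nergan:::tp_mean(tp, out),
           node = nd[[target]])
    }, mats[[target]])
    expect_lt(worst, 1e-4)
  }
})

test_that("attention gradients match finite differences", {
  set.seed(2)
  d <- 8L
  E <- rand_mat(5, d)
  Wq <- rand_mat(d, d); Wk <- rand_mat(d, d)
  Wv <- rand_mat(d, d); Wo <- rand_mat(d, d)
  worst <- fd_check(function(m) {
    tp <- nergan:::tape_new()
    En <- nergan:::tp_const(tp, E)
    out <- nergan:::tp_attention(tp, En, nergan:::tp_const(tp, m),
                                 nergan:::tp_const(tp, Wk),
                                 nergan:::tp_const(tp, Wv),
                                 nergan:::tp_const(tp, Wo),
                                 lens = c(3L, 2L), n_heads = 4L,
                                 rows_b = list(c(1L, 3L, 5L), c(2L, 4L)))
    list(tape = tp, loss = nergan:::tp_mean(tp, out),
         node = tp$nodes[[2]])
  }, Wq)
  expect_lt(worst, 1e-4)
})

test_that("conv, transposed conv and interpolation gradients check out", {
  set.seed(3)
  B <- 2L; L <- 8L; Cin <- 3L; Cout <- 4L
  x <- rand_mat(B * L, Cin)
  W <- rand_mat(3L * Cin, Cout)
  idx <- nergan:::conv_index(B, L, 3L, stride = 2L)
  worst <- fd_check(function(m) {
    tp <- nergan:::tape_new()
    xn <- nergan:::tp_const(tp, x)
    out <- nergan:::tp_conv1d(tp, xn, nergan:::tp_const(tp, m), NULL, idx,
                              act = "relu")
    list(tape = tp, loss = nergan:::tp_mean(tp, out), node = tp$nodes[[2]])
  }, W)
  expect_lt(worst, 1e-3) # relu kinks can inflate one-sided differences

  W1 <- rand_mat(Cin, Cout); W2 <- rand_mat(Cin, Cout)
  worst2 <- fd_check(function(m) {
    tp <- nergan:::tape_new()
    xn <- nergan:::tp_const(tp, x)
    out <- nergan:::tp_tconv1d(tp, xn, nergan:::tp_const(tp, m),
                               nergan:::tp_const(tp, W2), NULL, B)
    list(tape = tp, loss = nergan:::tp_mean(tp, out), node = tp$nodes[[2]])
  }, W1)
  expect_lt(worst2, 1e-4)

  ii <- nergan:::.interp_index(c(8L, 5L), 2L, 4L, 8L)
  worst3 <- fd_check(function(m) {
    tp <- nergan:::tape_new()
    xn <- nergan:::tp_const(tp, m)
    out <- nergan:::tp_interp_rows(tp, xn, ii$i1, ii$i2, ii$w)
    list(tape = tp, loss = nergan:::tp_mean(tp, out), node = xn)
  }, x)
  expect_lt(worst3, 1e-4)
})

test_that("layer norm and cross-entropy gradients check out", {
  set.seed(4)
  x <- rand_mat(6, 5)
  gn <- matrix(runif(5, 0.5, 1.5), 1)
  bn <- matrix(rnorm(5, 0, 0.2), 1)
  worst <- fd_check(function(m) {
    tp <- nergan:::tape_new()
    xn <- nergan:::tp_const(tp, m)
    out <- nergan:::tp_layernorm(tp, xn, nergan:::tp_const(tp, gn),
                                 nergan:::tp_const(tp, bn))
    list(tape = tp, loss = nergan:::tp_mean(tp, out), node = xn)
  }, x)
  expect_lt(worst, 1e-4)

  gold <- c(2L, 0L, 4L, 1L, 3L, 5L) # one padded row ignored
  worst2 <- fd_check(function(m) {
    tp <- nergan:::tape_new()
    xn <- nergan:::tp_const(tp, m)
    list(tape = tp, loss = nergan:::tp_ce(tp, xn, gold), node = xn)
  }, x)
  expect_lt(worst2, 1e-4)
})

test_that("conv index arithmetic: stride-2 halving and same padding", {
  idx <- nergan:::conv_index(1L, 8L, 3L, stride = 2L)
  expect_identical(nrow(idx), 4L)
  expect_identical(idx[1, ], c(0L, 1L, 2L))  # left edge zero-padded
  idx1 <- nergan:::conv_index(2L, 4L, 3L, stride = 1L)
  expect_identical(nrow(idx1), 8L)
  # row for (t=1, b=2) must reference only sequence-2 rows: 2,4,6,8 or 0
  r <- idx1[2, ]
  expect_true(all(r %in% c(0L, seq(2L, 8L, 2L))))
})

test_that("cross-tape gradient accumulation composes losses", {
  # the adversarial term is backpropagated from a second tape into nodes
  # of the first; the first tape's backward must then add its own loss
  set.seed(5)
  x <- rand_mat(3, 3)
  W <- rand_mat(3, 3)
  tp1 <- nergan:::tape_new()
  xn <- nergan:::tp_const(tp1, x)
  Wn <- nergan:::tp_const(tp1, W)
  h <- nergan:::tp_dense(tp1, xn, Wn, act = "tanh")
  tp2 <- nergan:::tape_new()
  l2 <- nergan:::tp_mean(tp2, nergan:::tp_act(tp2, h, "sigmoid"))
  nergan:::tape_backward(tp2, l2)
  l1 <- nergan:::tp_mean(tp1, h)
  nergan:::tape_backward(tp1, l1)
  g <- Wn$g
  # finite differences of the combined loss
  worst <- 0
  for (i in 1:4) {
    eps <- 1e-6
    f <- function(Wm) {
      h0 <- tanh(x %*% Wm)
      mean(h0) + mean(1 / (1 + exp(-h0)))
    }
    W1 <- W; W1[i] <- W1[i] + eps
    W2 <- W; W2[i] <- W2[i] - eps
    fd <- (f(W1) - f(W2)) / (2 * eps)
    worst <- max(worst, abs(fd - g[i]) / max(1e-8, abs(fd) + abs(g[i])))
  }
  expect_lt(worst, 1e-5)
})
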