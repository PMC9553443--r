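# Parameter store: named dense matrices with Adam state.  Parameters are
# created lazily on first use so each network component declares its own
# shapes where it is built.

pstore_new <- function() {
  ps <- new.env(parent = emptyenv())
  ps$val <- new.env(parent = emptyenv())
  ps$m <- new.env(parent = emptyenv())
  ps$s <- new.env(parent = emptyenv())
  ps$t <- 0L
  ps
}

# Xavier/Glorot uniform by default; "gain" init for layer-norm gains,
# "zeros" for biases, "normal" for embeddings.
p_init <- function(ps, name, nr, nc, init = "xavier", sd = 0.1) {
  if (!is.null(ps$val[[name]])) return(invisible(NULL))
  v <- switch(init,
    xavier = {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    },
    normal = matrix(stats::rnorm(nr * nc, 0, sd), nr, nc),
    zeros = matrix(0, nr, nc),
    ones = matrix(1, nr, nc),
    stop("unknown init: ", init)
  )
  ps$val[[name]] <- v
  ps$m[[name]] <- matrix(0, nr, nc)
  ps$s[[name]] <- matrix(0, nr, nc)
  invisible(NULL)
}

# leaf node for a parameter on the current tape (cached per tape)
P <- function(tp, ps, name, nr = NULL, nc = NULL, init = "xavier", sd = 0.1) {
  nd <- tp$pn[[name]]
  if (!is.null(nd)) return(nd)
  if (is.null(ps$val[[name]])) {
    stopifnot(!is.null(nr), !is.null(nc))
    p_init(ps, name, nr, nc, init, sd)
  }
  nd <- .emit(tp, ps$val[[name]])
  tp$pn[[name]] <- nd
  nd
}

# Adam update over every parameter touched on the tape that received a
# gradient; global-norm gradient clipping first.
adam_step <- function(ps, tp, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip = 5.0) {
  names <- ls(tp$pn)
  grads <- list()
  total <- 0
  for (nm in names) {
    if (is.null(ps$val[[nm]])) next # parameter of another store (frozen net)
    g <- tp$pn[[nm]]$g
    if (is.null(g)) next
    grads[[nm]] <- g
    total <- total + sum(g * g)
  }
  if (!length(grads)) return(invisible(0))
  gn <- sqrt(total)
  if (!is.finite(gn)) stop("non-finite gradient norm: training diverged")
  scale <- if (gn > clip) clip / gn else 1
  ps$t <- ps$t + 1L
  c1 <- 1 - beta1^ps$t
  c2 <- 1 - beta2^ps$t
  for (nm in names(grads)) {
    cpp_adam(ps$val[[nm]], ps$m[[nm]], ps$s[[nm]], grads[[nm]],
             lr, beta1, beta2, eps, c1, c2, scale)
  }
  invisible(gn)
}

pstore_export <- function(ps) {
  nm <- ls(ps$val)
  out <- lapply(nm, function(n) ps$val[[n]])
  names(out) <- nm
  out
}

pstore_import <- function(vals) {
  ps <- pstore_new()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    ps$val[[nm]] <- v
    ps$m[[nm]] <- matrix(0, nrow(v), ncol(v))
    ps$s[[nm]] <- matrix(0, nrow(v), ncol(v))
  }
  ps
}
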