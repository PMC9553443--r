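# Model fitting: alternating adversarial training of the conditioned
# generator and the convolutional discriminator (k discriminator steps, then
# one generator step, per minibatch), followed by a post-hoc CRF fit on the
# generator's label scores.

#' Adversarial losses
#'
#' Discriminator and generator-side adversarial losses of the conditional
#' min-max objective.  With discriminator scores \eqn{D(\cdot) \in (0,1)}:
#' \deqn{L_D = -\big[\mathrm{E}\log D(\mathrm{real}) +
#'       \mathrm{E}\log(1 - D(\mathrm{fake}))\big]}
#' The generator-side term is \eqn{\mathrm{E}\log(1 - D(\mathrm{fake}))}
#' (minimised), or \eqn{-\mathrm{E}\log D(\mathrm{fake})} for the
#' non-saturating variant.  Scores are clamped to
#' \eqn{[\epsilon, 1-\epsilon]} before the logarithms.  At the equilibrium
#' \eqn{D(\mathrm{real}) = D(\mathrm{fake}) = 1/2} the discriminator loss
#' equals \eqn{2\log 2}.
#'
#' @param d_real,d_fake numeric vectors of discriminator scores in (0, 1).
#' @param g_loss \code{"minimax"} or \code{"nonsaturating"}.
#' @param eps clamp width.
#' @return list with \code{loss_D} and \code{loss_G_adv}.
#' @export
adversarial_loss <- function(d_real, d_fake, g_loss = "minimax",
                             eps = 1e-7) {
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  loss_D <- -(mean(log(dr)) + mean(log(1 - df)))
  loss_G_adv <- if (g_loss == "minimax") mean(log(1 - df))
  else -mean(log(df))
  list(loss_D = loss_D, loss_G_adv = loss_G_adv)
}

#' Total generator loss
#'
#' Cross-entropy of the per-position label scores against the gold tags,
#' plus \code{lambda} times the adversarial generator term.  With
#' \code{lambda = 0} this is plain supervised sequence labelling.
#'
#' @param scores \code{T x n_tags} score matrix.
#' @param gold integer gold tag indices (1-based).
#' @param loss_G_adv adversarial generator term.
#' @param lambda weight of the adversarial term.
#' @return scalar loss.
#' @export
total_generator_loss <- function(scores, gold, loss_G_adv = 0,
                                 lambda = 1.0) {
  S <- scores - apply(scores, 1L, max)
  P <- exp(S)
  P <- P / rowSums(P)
  ce <- -mean(log(pmax(P[cbind(seq_len(nrow(S)), gold)], 1e-12)))
  ce + lambda * loss_G_adv
}

# one-hot gold label matrix in the batch layout
.onehot_gold <- function(bt, n_tags) {
  lab <- matrix(0, bt$B * bt$Tmax, n_tags)
  valid <- bt$gold > 0L
  lab[cbind(which(valid), bt$gold[valid])] <- 1
  lab
}

# split a batch-layout score matrix into per-sentence T_b x n_tags matrices
.split_scores <- function(S, bt) {
  lapply(seq_len(bt$B), function(b) {
    S[b + bt$B * (seq_len(bt$lens[b]) - 1L), , drop = FALSE]
  })
}

# eval-mode generator scores for a corpus; returns per-sentence matrices and
# gold index vectors
.score_corpus <- function(corpus, ps, vocab, catalog, cfg, seed_vec,
                          n_tags) {
  bts <- make_batches(corpus, vocab, catalog, cfg)
  scores <- list(); gold <- list()
  for (bt in bts) {
    tp <- tape_new(train = FALSE)
    gf <- generator_forward(tp, ps, bt, cfg, seed_vec, vocab$size, n_tags)
    scores <- c(scores, .split_scores(gf$scores$v, bt))
    gold <- c(gold, lapply(seq_len(bt$B), function(b) {
      bt$gold[b + bt$B * (seq_len(bt$lens[b]) - 1L)]
    }))
  }
  list(scores = scores, gold = gold)
}

#' Fit the adversarial NER model
#'
#' Trains the conditional adversarial sequence labeller on an annotated
#' corpus: per minibatch, \code{k_disc} discriminator updates with the
#' generator fixed, then one generator update with the discriminator fixed
#' (Adam for both, learning rate decayed multiplicatively per epoch).  The
#' generator loss is cross-entropy plus \code{lambda_adv} times the
#' adversarial term.  After training, a linear-chain CRF transition model is
#' fitted on the generator's label scores and used for decoding.
#'
#' @param corpus training corpus (see [read_conll()] / [synth_generate()]).
#' @param dev optional development corpus; entity-level metrics are recorded
#'   per epoch (argmax decoding) and at the end (CRF decoding).
#' @param config a [nergan_config()].
#' @param catalog an [entity_catalog()].
#' @param entity_vectors optional externally trained initial vectors for the
#'   entity-distribution seed (matrix \code{n_types x d_emb_seed}).
#' @param verbose print per-epoch progress.
#' @return object of class \code{nergan} with components \code{params},
#'   \code{disc_params}, \code{config}, \code{vocab}, \code{catalog},
#'   \code{seed}, \code{crf}, \code{history} (data frame with per-epoch
#'   \code{loss_D}, \code{loss_G}, \code{ce}, \code{dev_P}, \code{dev_R},
#'   \code{dev_F1}) and \code{dev_metrics} (final, CRF-decoded).
#' @export
nergan <- function(corpus, dev = NULL, config = nergan_config(),
                   catalog = entity_catalog(), entity_vectors = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(config, "nergan_config"))
  cl <- match.call()
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)

  vocab <- build_vocab(corpus)
  tags_all <- tag_set(catalog)
  n_tags <- length(tags_all)
  f <- count_frequencies(corpus, catalog)
  V <- init_entity_vectors(catalog, config$d_emb_seed,
                           rng_seed = config$rng_seed,
                           vectors = entity_vectors)
  seed_vec <- build_seed(catalog, f, V, mode = config$seed_mode,
                         rng_seed = config$rng_seed)
  bts <- make_batches(corpus, vocab, catalog, config)
  ps <- pstore_new()
  psd <- pstore_new()

  dev_tags <- if (!is.null(dev)) {
    lapply(corpus_sentences(dev), `[[`, "tags")
  }
  hist <- data.frame()
  lr <- config$lr
  crf <- NULL
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(bts))
    eD <- 0; eG <- 0; eCE <- 0; nb <- 0L
    for (bi in ord) {
      bt <- bts[[bi]]
      onehot <- .onehot_gold(bt, n_tags)
      # one generator forward serves both phases; the discriminator phase
      # uses its output detached (generator fixed), then the generator
      # phase backpropagates through the freshly updated discriminator
      tg <- tape_new(train = TRUE)
      gf <- generator_forward(tg, ps, bt, config, seed_vec, vocab$size,
                              n_tags)
      probs <- tp_softmax_rows(tg, gf$scores)
      probs <- tp_rowmask(tg, probs, bt$mask)
      adv_val <- 0
      if (config$lambda_adv > 0) {
        # --- discriminator step(s), generator fixed ---------------------
        for (kk in seq_len(config$k_disc)) {
          td <- tape_new(train = TRUE)
          fake <- tp_const(td, probs$v) # detached from the generator
          d_fake <- discriminator_forward(td, psd, fake, onehot, bt,
                                          config)
          d_real <- discriminator_forward(td, psd, tp_const(td, onehot),
                                          onehot, bt, config)
          l_r <- tp_mean(td, tp_log(td, d_real))
          l_f <- tp_mean(td, tp_log(td, tp_rsub(td, 1, d_fake)))
          loss_D <- tp_scale(td, tp_add(td, l_r, l_f), -1)
          if (!is.finite(loss_D$v[1L])) {
            stop(errorCondition("discriminator loss non-finite",
                                class = c("nergan_divergence", "error",
                                          "condition")))
          }
          tape_backward(td, loss_D)
          adam_step(psd, td, lr, clip = config$clip)
          eD <- eD + loss_D$v[1L]
        }
        # --- adversarial term through the updated discriminator ---------
        ta <- tape_new(train = TRUE)
        d_fake <- discriminator_forward(ta, psd, probs, onehot, bt, config)
        adv <- if (config$g_loss == "minimax") {
          tp_mean(ta, tp_log(ta, tp_rsub(ta, 1, d_fake)))
        } else {
          tp_scale(ta, tp_mean(ta, tp_log(ta, d_fake)), -1)
        }
        advw <- tp_scale(ta, adv, config$lambda_adv)
        adv_val <- adv$v[1L]
        # seeds the gradient of `probs` (a node of tg) across tapes
        tape_backward(ta, advw)
      }
      # --- generator step, discriminator fixed --------------------------
      ce <- tp_ce(tg, gf$scores, bt$gold)
      loss_G_val <- ce$v[1L] + config$lambda_adv * adv_val
      if (!is.finite(loss_G_val)) {
        stop(errorCondition("generator loss non-finite",
                            class = c("nergan_divergence", "error",
                                      "condition")))
      }
      tape_backward(tg, ce)
      adam_step(ps, tg, lr, clip = config$clip)
      eG <- eG + loss_G_val
      eCE <- eCE + ce$v[1L]
      nb <- nb + 1L
    }
    row <- data.frame(epoch = epoch, loss_D = eD / max(nb, 1L),
                      loss_G = eG / nb, ce = eCE / nb,
                      dev_P = NA_real_, dev_R = NA_real_,
                      dev_F1 = NA_real_)
    if (!is.null(dev)) {
      sc <- .score_corpus(dev, ps, vocab, catalog, config, seed_vec,
                          n_tags)
      pred <- lapply(sc$scores, function(S) {
        tags_all[max.col(S, ties.method = "first")]
      })
      m <- evaluate_ner(pred, dev_tags, per_type = FALSE)
      row$dev_P <- m$overall["P"]; row$dev_R <- m$overall["R"]
      row$dev_F1 <- m$overall["F1"]
    }
    hist <- rbind(hist, row)
    if (config$joint_crf || epoch == config$epochs) {
      crf <- .fit_crf_now(corpus, ps, vocab, catalog, config, seed_vec,
                          n_tags, tags_all)
    }
    if (verbose) {
      message(sprintf(
        "epoch %2d  loss_D %.4f  loss_G %.4f  ce %.4f  dev_F1 %s",
        epoch, row$loss_D, row$loss_G, row$ce,
        ifelse(is.na(row$dev_F1), "-", sprintf("%.2f", row$dev_F1))))
    }
    lr <- lr * config$lr_decay
  }

  obj <- structure(list(
    params = pstore_export(ps), disc_params = pstore_export(psd),
    config = config, vocab = vocab, catalog = catalog, seed = seed_vec,
    seed_f = f, entity_vectors = V, crf = crf, history = hist,
    call = cl
  ), class = "nergan")
  if (!is.null(dev)) {
    pred <- predict(obj, dev)
    obj$dev_metrics <- evaluate_ner(pred, dev_tags)
  }
  obj
}

.fit_crf_now <- function(corpus, ps, vocab, catalog, cfg, seed_vec, n_tags,
                         tags_all) {
  sub <- corpus
  n <- length(corpus_sentences(corpus))
  if (n > cfg$crf_sentences) {
    sub <- synth_subsample(corpus, cfg$crf_sentences / n,
                           rng_seed = cfg$rng_seed)
  }
  sc <- .score_corpus(sub, ps, vocab, catalog, cfg, seed_vec, n_tags)
  crf_fit(sc$scores, sc$gold, tags_all, iters = cfg$crf_iters,
          lr = cfg$crf_lr)
}

#' Predict BIO tags for a corpus
#'
#' Runs the trained generator over the corpus and decodes the label score
#' sequences with the fitted CRF (Viterbi).
#'
#' @param object a fitted \code{nergan} model.
#' @param corpus an annotated corpus (tags may be all \code{"O"}).
#' @param type \code{"tags"} (list of BIO tag vectors, one per sentence),
#'   \code{"entities"} (list of span data frames), \code{"scores"} (list of
#'   raw score matrices), or \code{"corpus"} (the input corpus with
#'   predicted tags substituted).
#' @param ... unused.
#' @export
predict.nergan <- function(object, corpus, type = c("tags", "entities",
                                                    "scores", "corpus"),
                           ...) {
  type <- match.arg(type)
  ps <- pstore_import(object$params)
  n_tags <- length(object$crf$tags)
  sc <- .score_corpus(corpus, ps, object$vocab, object$catalog,
                      object$config, object$seed, n_tags)
  if (type == "scores") return(sc$scores)
  paths <- lapply(sc$scores, viterbi_decode, params = object$crf)
  tags <- lapply(paths, function(p) object$crf$tags[p])
  if (type == "tags") return(tags)
  if (type == "entities") return(lapply(tags, extract_entities))
  # write tags back into the hierarchy
  si <- 0L
  docs <- lapply(corpus, function(doc) {
    chapters <- lapply(doc$chapters, function(ch) {
      lapply(ch, function(pa) {
        lapply(pa, function(se) {
          si <<- si + 1L
          new_sentence(se$chars, tags[[si]])
        })
      })
    })
    new_document(doc$doc_type, chapters)
  })
  new_corpus(docs)
}

#' @export
print.nergan <- function(x, ...) {
  cat("Conditional adversarial NER model\n")
  cat("  granularities:", paste(x$config$granularities, collapse = "+"),
      "\n")
  cat("  main input:", x$config$main_input,
      " condition:", x$config$condition,
      " seed:", x$config$seed_mode, "\n")
  cat("  vocabulary:", x$vocab$size, "characters;",
      length(x$crf$tags), "tags\n")
  cat("  epochs:", nrow(x$history), " final loss_G:",
      sprintf("%.4f", x$history$loss_G[nrow(x$history)]), "\n")
  if (!is.null(x$dev_metrics)) {
    m <- x$dev_metrics$overall
    cat(sprintf("  dev P/R/F1: %.2f / %.2f / %.2f\n", m["P"], m["R"],
                m["F1"]))
  }
  invisible(x)
}

#' @export
summary.nergan <- function(object, ...) {
  out <- list(config = object$config, history = object$history,
              dev_metrics = object$dev_metrics,
              n_params = sum(vapply(object$params, length, numeric(1))) +
                sum(vapply(object$disc_params, length, numeric(1))),
              seed_p = attr(object$seed, "p"))
  class(out) <- "summary.nergan"
  out
}

#' @export
print.summary.nergan <- function(x, ...) {
  cat("Conditional adversarial NER model —", x$n_params,
      "trainable weights\n\n")
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  if (!is.null(x$dev_metrics)) {
    cat("\nDev metrics (CRF-decoded, entity level):\n")
    m <- x$dev_metrics$overall
    cat(sprintf("  P %.2f  R %.2f  F1 %.2f\n", m["P"], m["R"], m["F1"]))
    if (!is.null(x$dev_metrics$per_type)) {
      print(x$dev_metrics$per_type, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
coef.nergan <- function(object, ...) object$params

#' @export
plot.nergan <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss_G, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training losses")
  graphics::lines(h$epoch, h$loss_D, lty = 2)
  graphics::legend("topright", legend = c("generator", "discriminator"),
                   lty = c(1, 2), bty = "n")
  if (!all(is.na(h$dev_F1))) {
    graphics::plot(h$epoch, h$dev_F1, type = "l", xlab = "epoch",
                   ylab = "dev F1 (%)", main = "dev entity F1")
  }
  invisible(x)
}
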