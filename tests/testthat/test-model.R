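# Model assembly: losses, forward contracts, a training smoke run, model
# persistence and the command-line layer.

n_tags <- length(nergan:::tag_set(entity_catalog()))

test_that("adversarial losses: closed forms and gradient direction", {
  eq <- adversarial_loss(0.5, 0.5)
  expect_equal(eq$loss_D, 2 * log(2), tolerance = 1e-12)
  # a perfect discriminator drives the loss to (clamped) zero
  perfect <- adversarial_loss(1, 0)
  expect_lt(perfect$loss_D, 1e-5)
  # raising the fake score raises the discriminator loss
  expect_gt(adversarial_loss(0.5, 0.6)$loss_D,
            adversarial_loss(0.5, 0.5)$loss_D)
  # generator-side terms
  expect_equal(adversarial_loss(0.5, 0.25)$loss_G_adv, log(0.75),
               tolerance = 1e-12)
  expect_equal(adversarial_loss(0.5, 0.25,
                                g_loss = "nonsaturating")$loss_G_adv,
               -log(0.25), tolerance = 1e-12)
})

test_that("total generator loss reduces to cross-entropy at lambda 0", {
  n_tags <- 40L
  scores <- matrix(0, 2, n_tags) # uniform scores
  gold <- c(3L, 17L)
  expect_equal(total_generator_loss(scores, gold, loss_G_adv = 5,
                                    lambda = 0),
               log(n_tags), tolerance = 1e-12)
  expect_equal(total_generator_loss(scores, gold, loss_G_adv = 2,
                                    lambda = 0.5),
               log(n_tags) + 1, tolerance = 1e-12)
  # saturated gold scores: loss approaches 0
  sat <- matrix(-50, 2, n_tags)
  sat[cbind(1:2, gold)] <- 50
  expect_lt(total_generator_loss(sat, gold, 0, 0), 1e-10)
})

test_that("generator output length equals input text length", {
  g <- memorizable_corpus(3L)
  cfg <- tiny_config()
  v <- build_vocab(g)
  catl <- entity_catalog()
  bts <- nergan:::make_batches(g, v, catl, cfg)
  fvec <- count_frequencies(g, catl)
  V <- init_entity_vectors(catl, cfg$d_emb_seed, 1L)
  sv <- build_seed(catl, fvec, V)
  for (bt in bts) {
    tp <- nergan:::tape_new()
    gf <- nergan:::generator_forward(tp, nergan:::pstore_new(), bt, cfg,
                                     sv, v$size, n_tags)
    expect_identical(nrow(gf$scores$v), bt$B * bt$Tmax)
    sc <- nergan:::.split_scores(gf$scores$v, bt)
    expect_identical(vapply(sc, nrow, integer(1)), bt$lens)
    # padded rows carry zero scores
    pad <- bt$mask == 0
    if (any(pad)) {
      expect_equal(max(abs(gf$scores$v[pad, ])), 0)
    }
  }
})

test_that("ablation switches change the forward path but not the contract", {
  g <- memorizable_corpus(4L)
  v <- build_vocab(g)
  catl <- entity_catalog()
  fvec <- count_frequencies(g, catl)
  for (over in list(list(main_input = "noise"),
                    list(condition = "L"),
                    list(granularities = c("sentence", "paragraph")),
                    list(granularities = c("char", "sentence")),
                    list(encoder_block = "canonical"),
                    list(positional_encoding = "sinusoidal"),
                    list(seed_mode = "random"))) {
    cfg <- do.call(tiny_config, over)
    V <- init_entity_vectors(catl, cfg$d_emb_seed, 1L)
    sv <- build_seed(catl, fvec, V, mode = cfg$seed_mode)
    bt <- nergan:::make_batches(g, v, catl, cfg)[[1]]
    tp <- nergan:::tape_new()
    set.seed(1)
    gf <- nergan:::generator_forward(tp, nergan:::pstore_new(), bt, cfg,
                                     sv, v$size, n_tags)
    expect_identical(dim(gf$scores$v), c(bt$B * bt$Tmax, n_tags))
    expect_true(all(is.finite(gf$scores$v)))
  }
})

test_that("discriminator scores lie in (0,1) and are deterministic", {
  g <- memorizable_corpus(5L)
  cfg <- tiny_config()
  v <- build_vocab(g)
  catl <- entity_catalog()
  bt <- nergan:::make_batches(g, v, catl, cfg)[[1]]
  oh <- nergan:::.onehot_gold(bt, n_tags)
  psd <- nergan:::pstore_new()
  set.seed(2)
  run_disc <- function() {
    tp <- nergan:::tape_new()
    nergan:::discriminator_forward(tp, psd, nergan:::tp_const(tp, oh), oh,
                                   bt, cfg)$v
  }
  d1 <- run_disc()
  d2 <- run_disc()
  expect_true(all(d1 > 0 & d1 < 1))
  expect_identical(d1, d2)
})

test_that("one adversarial epoch runs with finite losses and history", {
  g <- memorizable_corpus(6L)
  fit <- nergan(g, dev = g, config = tiny_config(rng_seed = 2L))
  expect_s3_class(fit, "nergan")
  h <- fit$history
  expect_identical(nrow(h), 1L)
  expect_true(all(is.finite(c(h$loss_D, h$loss_G, h$ce))))
  expect_false(is.na(h$dev_F1))
  expect_s3_class(fit$crf, "crf_params")
})

test_that("gradient flows into every generator parameter group", {
  g <- memorizable_corpus(7L)
  cfg <- tiny_config()
  v <- build_vocab(g)
  catl <- entity_catalog()
  bt <- nergan:::make_batches(g, v, catl, cfg)[[1]]
  fvec <- count_frequencies(g, catl)
  V <- init_entity_vectors(catl, cfg$d_emb_seed, 1L)
  sv <- build_seed(catl, fvec, V)
  ps <- nergan:::pstore_new()
  tp <- nergan:::tape_new(train = TRUE)
  set.seed(3)
  gf <- nergan:::generator_forward(tp, ps, bt, cfg, sv, v$size, n_tags)
  ce <- nergan:::tp_ce(tp, gf$scores, bt$gold)
  nergan:::tape_backward(tp, ce)
  for (nm in ls(tp$pn)) {
    expect_false(is.null(tp$pn[[nm]]$g), label = paste("grad of", nm))
    expect_gt(sum(abs(tp$pn[[nm]]$g)), 0)
  }
})

test_that("supervised training decreases CE on a memorizable corpus", {
  g <- memorizable_corpus(11L)
  cfg <- tiny_config(lambda_adv = 0, epochs = 5L, lr = 1e-3,
                     dropout = 0, rng_seed = 4L)
  fit <- nergan(g, config = cfg)
  ce <- fit$history$ce
  expect_lt(ce[5], ce[1])
  expect_true(all(diff(ce) < 0.02)) # essentially non-increasing
})

test_that("a fitted model predicts aligned tags and survives save/load", {
  g <- memorizable_corpus(8L)
  fit <- cached("tiny_fit", nergan(g, dev = g,
                                   config = tiny_config(rng_seed = 5L)))
  tags <- predict(fit, g)
  sents <- nergan:::corpus_sentences(g)
  expect_identical(length(tags), length(sents))
  expect_identical(lengths(tags), lengths(lapply(sents, `[[`, "chars")))
  expect_identical(predict(fit, g), tags) # idempotent
  ents <- predict(fit, g, type = "entities")
  expect_true(all(vapply(ents, is.data.frame, logical(1))))
  pc <- predict(fit, g, type = "corpus")
  expect_identical(lapply(nergan:::corpus_sentences(pc), `[[`, "tags"),
                   tags)

  dir <- tempfile("model")
  nergan:::save_model(fit, dir)
  back <- nergan:::load_model(dir)
  expect_identical(predict(back, g), tags)

  # print/summary/plot/coef methods run
  expect_output(print(fit), "adversarial NER")
  expect_output(print(summary(fit)), "Dev metrics")
  expect_type(coef(fit), "list")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("the command-line layer wires synth, train, predict, evaluate", {
  dir <- tempfile("cli")
  dir.create(dir)
  synth_dir <- file.path(dir, "synth")
  expect_identical(cli_main(c("synth", "--regime", "easy", "--seed", "3",
                              "--out", synth_dir)), 0L)
  expect_true(file.exists(file.path(synth_dir, "train.bio")))
  expect_true(file.exists(file.path(synth_dir, "train_truth.json")))

  cfgf <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(d_model = 16L, gru_hidden = 8L,
                            article_dim = 8L, d_emb_seed = 4L,
                            seed_c0 = 4L,
                            enc_channels = c(4L, 4L, 8L, 8L, 8L, 8L),
                            dec_channels = rep(8L, 6L),
                            d_cond = 6L, d_main = 6L,
                            disc_channels = rep(8L, 7L),
                            batch_size = 4L, epochs = 1L,
                            crf_iters = 3L, crf_sentences = 10L),
                       cfgf, auto_unbox = TRUE)
  model_dir <- file.path(dir, "model")
  expect_identical(cli_main(c("train", "--config", cfgf,
                              "--train", file.path(synth_dir, "train.bio"),
                              "--dev", file.path(synth_dir, "dev.bio"),
                              "--out", model_dir)), 0L)
  expect_true(file.exists(file.path(model_dir, "model.json")))
  expect_true(file.exists(file.path(model_dir, "history.csv")))

  pred <- file.path(dir, "pred.bio")
  expect_identical(cli_main(c("predict", "--model", model_dir,
                              "--input", file.path(synth_dir, "test.bio"),
                              "--out", pred)), 0L)
  # output line structure mirrors the input character count
  n_in <- length(nergan:::corpus_chars(
    read_conll(file.path(synth_dir, "test.bio"))))
  n_out <- length(nergan:::corpus_chars(read_conll(pred,
                                                   validate = FALSE)))
  expect_identical(n_in, n_out)

  metf <- file.path(dir, "metrics.json")
  expect_identical(cli_main(c("evaluate", "--pred", pred, "--gold",
                              file.path(synth_dir, "test.bio"),
                              "--out", metf)), 0L)
  m <- jsonlite::fromJSON(metf)
  expect_true(all(c("P", "R", "F1") %in% names(m$overall)))

  # bad configuration key -> config error exit code
  badf <- file.path(dir, "bad.json")
  jsonlite::write_json(list(nonsense_key = 1), badf, auto_unbox = TRUE)
  expect_identical(suppressMessages(
    cli_main(c("train", "--config", badf, "--train",
               file.path(synth_dir, "train.bio")))), 2L)
  # unreadable data -> data error exit code
  expect_identical(suppressWarnings(suppressMessages(
    cli_main(c("evaluate", "--pred", "/nonexistent.bio", "--gold",
               file.path(synth_dir, "test.bio"))))), 3L)
})

test_that("run configurations validate their arguments", {
  expect_error(nergan_config(d_model = 65L), "divisible")
  expect_error(nergan_config(granularities = "char"), "sentence")
  expect_error(nergan_config(seed_len = 48L), "power of two")
  expect_error(nergan_config(k_disc = 0L), "k_disc")
  cfg <- nergan_config()
  expect_identical(cfg$epochs, 20L)
  expect_identical(cfg$lr, 1e-4)
  expect_identical(cfg$lr_decay, 0.95)
  expect_identical(cfg$dropout, 0.3)
  expect_identical(cfg$k_disc, 1L)
  expect_identical(cfg$n_layers, 6L)
  expect_identical(cfg$n_heads, 8L)
})
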