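# Shared fixtures and a cache for training runs reused across test files
# (testthat runs the suite in one process, so heavy fits are computed once).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

config_with <- function(defaults, dots) {
  do.call(nergan_config, utils::modifyList(defaults, dots))
}

# tiny config for fast structural tests
tiny_config <- function(...) {
  config_with(list(d_model = 16L, gru_hidden = 8L, article_dim = 8L,
                   d_emb_seed = 4L, seed_c0 = 4L,
                   enc_channels = c(4L, 4L, 8L, 8L, 8L, 8L),
                   dec_channels = c(8L, 8L, 8L, 8L, 8L, 8L),
                   d_cond = 6L, d_main = 6L, disc_channels = rep(8L, 7L),
                   batch_size = 4L, epochs = 1L, crf_iters = 5L,
                   crf_sentences = 20L), list(...))
}

# the desk profile used for full-scale end-to-end runs: architecture sized
# for one CPU, learning rate matched to the small update budget
desk_config <- function(...) {
  config_with(list(d_model = 64L, gru_hidden = 32L, article_dim = 32L,
                   disc_channels = rep(32L, 7L), lr = 1e-3), list(...))
}

# easy-regime corpora: separable lexicons shared between train and dev
easy_pair <- function(n_train_chapters = 20L, n_dev_chapters = 4L,
                      lang_seed = 101L) {
  mk <- function(n_ch, ts) synth_config(
    regime = "easy", n_chapters = n_ch, paragraphs_per_chapter = 5L,
    sentences_per_paragraph = 5L, rng_seed = lang_seed, text_seed = ts)
  list(train = synth_generate(mk(n_train_chapters, lang_seed * 10L + 1L))$corpus,
       dev = synth_generate(mk(n_dev_chapters, lang_seed * 10L + 2L))$corpus)
}

# hard-regime corpora for the directional ablations: few enough lexicon
# entries that 150 sentences give several examples per entry, with
# cue-disambiguated ambiguous entries
hard_pair <- function(lang_seed = 301L) {
  mk <- function(n_ch, ts) synth_config(
    regime = "hard", n_chapters = n_ch, paragraphs_per_chapter = 5L,
    sentences_per_paragraph = 5L,
    active_types = c("ZY", "ZZ2", "MX", "SX", "FJ", "BY"),
    lexicon_size = 8L, entity_density = 0.7, ambiguity_rate = 0.3,
    rng_seed = lang_seed, text_seed = ts)
  list(train = synth_generate(mk(6L, lang_seed * 10L + 1L))$corpus,
       dev = synth_generate(mk(2L, lang_seed * 10L + 2L))$corpus)
}

# a 10-sentence memorizable corpus for the supervised sanity micro-run
memorizable_corpus <- function(seed = 11L) {
  synth_generate(synth_config(regime = "easy", n_chapters = 1L,
                              paragraphs_per_chapter = 2L,
                              sentences_per_paragraph = 5L,
                              rng_seed = seed))$corpus
}

# full-profile easy run (criterion-scale); memoised per seed.  Dev metrics
# are computed once at the end (CRF decoding) rather than per epoch.
easy_run <- function(seed) {
  cached(paste0("easy_run_", seed), {
    pair <- cached("easy_pair", easy_pair())
    fit <- nergan(pair$train,
                  config = desk_config(rng_seed = as.integer(seed)))
    m <- evaluate_ner(predict(fit, pair$dev), gold_tags_of(pair$dev))
    fit$dev_metrics <- m
    fit
  })
}

gold_tags_of <- function(corpus) {
  lapply(nergan:::corpus_sentences(corpus), `[[`, "tags")
}

# ablation benchmark profile on the hard-regime corpus; memoised per
# (config key, seed)
hard_run_f1 <- function(seed, key, ...) {
  cached(paste0("hard_", key, "_", seed), {
    pair <- cached("hard_pair", hard_pair())
    cfg <- desk_config(epochs = 9L, crf_sentences = 40L,
                       crf_iters = 20L, rng_seed = as.integer(seed), ...)
    fit <- nergan(pair$train, config = cfg)
    m <- evaluate_ner(predict(fit, pair$dev), gold_tags_of(pair$dev),
                      per_type = FALSE)
    unname(m$overall["F1"])
  })
}
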