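# Model/run configuration with defaults.  The published training profile is
# kept as the default (Adam, lr 1e-4 for both networks, multiplicative lr
# decay 0.95 per epoch, dropout 0.3, 20 epochs, k = 1 discriminator step);
# architectural sizes are configurable with a desk profile documented in the
# methods vignette.

#' Model configuration
#'
#' @param d_model Transformer model width of the sentence/paragraph
#'   encoders; must be divisible by \code{n_heads}.
#' @param n_heads attention heads (8).
#' @param n_layers stacked encoding layers (6).
#' @param gru_hidden hidden width of the character-position GRU encoder.
#' @param article_dim output width of the chapter-granularity CNN encoder.
#' @param d_emb_seed embedding width of each entity-type initial vector;
#'   the seed vector has length \code{19 * d_emb_seed}.
#' @param dropout dropout rate (applied after embeddings, after each
#'   encoder layer, and in the chapter encoder's fully connected layer).
#' @param encoder_block \code{"paper"}: the as-printed encoder block
#'   (normalise the residual sum before the feed-forward and again after);
#'   \code{"canonical"}: the standard Transformer block.
#' @param positional_encoding \code{"none"} (default; the character-granularity
#'   GRU is the positional mechanism) or \code{"sinusoidal"}.
#' @param share_embeddings share one character embedding table across the
#'   character/sentence/paragraph/chapter encoders.
#' @param granularities subset of
#'   \code{c("char", "sentence", "paragraph", "chapter")} switched on; at
#'   least one of \code{"sentence"}, \code{"paragraph"} is required (they
#'   carry the attention data).
#' @param seed_mode \code{"distribution"} (entity-distribution seed) or
#'   \code{"random"} (ablation: random blocks).
#' @param main_input \code{"attention"} (fused sentence+paragraph attention
#'   data) or \code{"noise"} (ablation: white noise of the same shape).
#' @param condition generator condition: \code{"Y"} (fused multigranularity
#'   features + encoded seed) or \code{"L"} (ablation: gold labels during
#'   training, zeros at prediction time).
#' @param lr,lr_decay,epochs,k_disc,batch_size,lambda_adv,g_loss,clip
#'   training profile: Adam learning rate for both networks, per-epoch
#'   multiplicative decay, training epochs, discriminator steps per
#'   generator step, minibatch size (whole paragraphs are grouped until the
#'   batch holds at least this many sentences), weight of the adversarial
#'   term added to the cross-entropy, generator adversarial loss form
#'   (\code{"minimax"}: minimise \code{log(1 - D(fake))};
#'   \code{"nonsaturating"}: minimise \code{-log D(fake)}), global
#'   gradient-norm clip.
#' @param enc_channels,dec_channels,seed_len,seed_c0,d_cond,d_main U-shaped
#'   generator sizes: encoder/decoder channel widths per level, the length
#'   and width of the pseudo-sequence the seed is projected to, the width
#'   the fused condition is projected to, and the width the main attention
#'   input is projected to.
#' @param disc_channels discriminator conv channels (7 layers).
#' @param crf_iters,crf_lr,crf_sentences CRF transition fit: optimisation
#'   steps, learning rate, and the maximum number of training sentences used
#'   as emission examples.
#' @param joint_crf fit the CRF jointly during training instead of
#'   post hoc (default FALSE: the CRF is fitted on generator scores after
#'   adversarial training reaches its steady state).
#' @param rng_seed integer master seed; all randomness in fitting flows from
#'   it.
#' @return object of class \code{nergan_config}.
#' @export
nergan_config <- function(d_model = 128L,
                          n_heads = 8L,
                          n_layers = 6L,
                          gru_hidden = 64L,
                          article_dim = 64L,
                          d_emb_seed = 16L,
                          dropout = 0.3,
                          encoder_block = c("paper", "canonical"),
                          positional_encoding = c("none", "sinusoidal"),
                          share_embeddings = FALSE,
                          granularities = c("char", "sentence", "paragraph",
                                            "chapter"),
                          seed_mode = c("distribution", "random"),
                          main_input = c("attention", "noise"),
                          condition = c("Y", "L"),
                          lr = 1e-4,
                          lr_decay = 0.95,
                          epochs = 20L,
                          k_disc = 1L,
                          batch_size = 8L,
                          lambda_adv = 1.0,
                          g_loss = c("minimax", "nonsaturating"),
                          clip = 5.0,
                          enc_channels = c(16L, 16L, 32L, 32L, 64L, 64L),
                          dec_channels = c(64L, 48L, 48L, 48L, 48L, 48L),
                          seed_len = 64L,
                          seed_c0 = 8L,
                          d_cond = 64L,
                          d_main = 64L,
                          disc_channels = rep(48L, 7L),
                          crf_iters = 40L,
                          crf_lr = 0.2,
                          crf_sentences = 120L,
                          joint_crf = FALSE,
                          rng_seed = 1L) {
  encoder_block <- match.arg(encoder_block)
  positional_encoding <- match.arg(positional_encoding)
  seed_mode <- match.arg(seed_mode)
  main_input <- match.arg(main_input)
  condition <- match.arg(condition)
  g_loss <- match.arg(g_loss)
  granularities <- match.arg(granularities,
                             c("char", "sentence", "paragraph", "chapter"),
                             several.ok = TRUE)
  if (d_model %% n_heads != 0L) {
    stop("d_model must be divisible by n_heads")
  }
  if (!any(c("sentence", "paragraph") %in% granularities)) {
    stop("granularities must include 'sentence' or 'paragraph'")
  }
  if (length(enc_channels) != 6L || length(dec_channels) != 6L) {
    stop("enc_channels and dec_channels must have 6 levels")
  }
  if (length(disc_channels) != 7L) stop("disc_channels must have 7 layers")
  if (k_disc < 1L) stop("k_disc must be >= 1")
  if (seed_len != 2L^round(log2(seed_len)) || seed_len < 64L) {
    stop("seed_len must be a power of two, at least 64")
  }
  structure(list(
    d_model = as.integer(d_model), n_heads = as.integer(n_heads),
    n_layers = as.integer(n_layers), gru_hidden = as.integer(gru_hidden),
    article_dim = as.integer(article_dim),
    d_emb_seed = as.integer(d_emb_seed), dropout = dropout,
    encoder_block = encoder_block,
    positional_encoding = positional_encoding,
    share_embeddings = share_embeddings, granularities = granularities,
    seed_mode = seed_mode, main_input = main_input, condition = condition,
    lr = lr, lr_decay = lr_decay, epochs = as.integer(epochs),
    k_disc = as.integer(k_disc), batch_size = as.integer(batch_size),
    lambda_adv = lambda_adv, g_loss = g_loss, clip = clip,
    enc_channels = as.integer(enc_channels),
    dec_channels = as.integer(dec_channels),
    seed_len = as.integer(seed_len), seed_c0 = as.integer(seed_c0),
    d_cond = as.integer(d_cond), d_main = as.integer(d_main),
    disc_channels = as.integer(disc_channels),
    crf_iters = as.integer(crf_iters), crf_lr = crf_lr,
    crf_sentences = as.integer(crf_sentences),
    joint_crf = joint_crf, rng_seed = as.integer(rng_seed)
  ), class = "nergan_config")
}

# update a config with named overrides, re-validating
config_update <- function(cfg, ...) {
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  do.call(nergan_config, unclass(cfg))
}

# read a config from JSON/YAML-like JSON file; unknown keys rejected
#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected with the offending key named.
#' @param path JSON file of configuration keys.
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path)
  bad <- setdiff(names(obj), names(formals(nergan_config)))
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  do.call(nergan_config, obj)
}
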