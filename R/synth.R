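# Synthetic annotated-corpus generator.
#
# Emulates the statistical structure the model assumes about classical
# medical text: character-level text with no whitespace, a
# chapter/paragraph/sentence hierarchy, multi-character entities drawn from
# per-type lexicons over 19 types with controllable frequency skew, sparse
# and irregular entity placement, and (in the hard regime) surface forms
# shared between two types whose gold type is resolvable only from a
# left-context cue character.  The alphabet is a synthetic CJK code-point
# range; the model is character-agnostic, so no real lexical resources are
# involved.

#' Synthetic corpus configuration
#'
#' @param regime \code{"easy"} (separable: entity surface forms are unique to
#'   one type and built from characters that never occur as background) or
#'   \code{"hard"} (a fraction of lexicon entries is shared between two
#'   types, disambiguated only by a type-specific cue character immediately
#'   before the entity; lower entity density).
#' @param n_chapters,paragraphs_per_chapter,sentences_per_paragraph corpus
#'   hierarchy sizes.
#' @param sentence_len integer range (lo, hi) of characters per sentence.
#' @param alphabet_size number of distinct characters available.
#' @param active_types catalog codes allowed to occur (frequency weights of
#'   the rest are zero).
#' @param type_weights non-negative weights over \code{active_types}
#'   (recycled/normalised); controls the entity-type frequency skew.
#' @param entity_density probability in \code{[0,1]} that each of
#'   \code{max_entities} slots of a sentence receives an entity.
#' @param max_entities maximum entities per sentence.
#' @param entity_len range of entity lengths in characters (1--4).
#' @param lexicon_size entries per type lexicon.
#' @param ambiguity_rate fraction of lexicon entries shared between two
#'   types.
#' @param doc_type document type tag of the generated documents.
#' @param rng_seed integer seed; generation is a deterministic function of
#'   the configuration.  The per-type lexicons are keyed by this seed, so
#'   corpora sharing \code{rng_seed} share one synthetic "language".
#' @param text_seed optional separate seed for the text sample (hierarchy,
#'   sentence lengths, entity placement).  Defaults to \code{rng_seed}.
#'   Distinct \code{text_seed}s with one \code{rng_seed} give disjoint
#'   train/dev/test samples over the same lexicons.
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(regime = c("easy", "hard"),
                         n_chapters = 4L,
                         paragraphs_per_chapter = 5L,
                         sentences_per_paragraph = 5L,
                         sentence_len = c(8L, 14L),
                         alphabet_size = 420L,
                         active_types = NULL,
                         type_weights = NULL,
                         entity_density = NULL,
                         max_entities = 2L,
                         entity_len = c(1L, 4L),
                         lexicon_size = 12L,
                         ambiguity_rate = NULL,
                         doc_type = "comprehensive",
                         rng_seed = 1L,
                         text_seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(active_types)) {
    active_types <- if (regime == "easy") {
      c("ZY", "ZZ2", "MX", "SX", "FJ")
    } else {
      c("ZY", "ZZ2", "MX", "SX", "FJ", "BY", "JB", "ZH", "YX", "GJ")
    }
  }
  if (is.null(type_weights)) type_weights <- rep(1, length(active_types))
  if (is.null(entity_density)) {
    entity_density <- if (regime == "easy") 0.8 else 0.5
  }
  if (is.null(ambiguity_rate)) {
    ambiguity_rate <- if (regime == "easy") 0 else 0.35
  }
  stopifnot(length(type_weights) == length(active_types),
            all(type_weights >= 0), any(type_weights > 0),
            entity_density >= 0, entity_density <= 1,
            entity_len[1] >= 1L, entity_len[2] <= 4L)
  structure(list(
    regime = regime, n_chapters = n_chapters,
    paragraphs_per_chapter = paragraphs_per_chapter,
    sentences_per_paragraph = sentences_per_paragraph,
    sentence_len = as.integer(sentence_len),
    alphabet_size = as.integer(alphabet_size),
    active_types = active_types,
    type_weights = type_weights / sum(type_weights),
    entity_density = entity_density, max_entities = as.integer(max_entities),
    entity_len = as.integer(entity_len),
    lexicon_size = as.integer(lexicon_size),
    ambiguity_rate = ambiguity_rate,
    doc_type = doc_type, rng_seed = as.integer(rng_seed),
    text_seed = as.integer(if (is.null(text_seed)) rng_seed else text_seed)
  ), class = "synth_config")
}

# character pools: disjoint ranges of a synthetic CJK block
.synth_alphabet <- function(cfg) {
  chars <- intToUtf8(0x4E00 + seq_len(cfg$alphabet_size) - 1L,
                     multiple = TRUE)
  n_ent <- min(length(cfg$active_types) * cfg$lexicon_size * 4L,
               cfg$alphabet_size - length(cfg$active_types) - 60L)
  n_cue <- length(cfg$active_types)
  list(entity = chars[seq_len(n_ent)],
       cue = chars[n_ent + seq_len(n_cue)],
       background = chars[(n_ent + n_cue + 1L):length(chars)])
}

# deterministic per-type lexicons; ambiguous entries are shared between a
# type and its successor in active_types order
.synth_lexicons <- function(cfg) {
  ab <- .synth_alphabet(cfg)
  k <- length(cfg$active_types)
  with_seed(cfg$rng_seed * 13L + 7L, {
    pool <- sample(ab$entity)
    lex <- vector("list", k)
    names(lex) <- cfg$active_types
    ptr <- 1L
    for (i in seq_len(k)) {
      entries <- character(cfg$lexicon_size)
      for (j in seq_len(cfg$lexicon_size)) {
        len <- sample(cfg$entity_len[1]:cfg$entity_len[2], 1L)
        if (ptr + len - 1L > length(pool)) {
          stop("alphabet too small for separable lexicons: raise ",
               "alphabet_size or lower lexicon_size")
        }
        entries[j] <- paste0(pool[ptr:(ptr + len - 1L)], collapse = "")
        ptr <- ptr + len
      }
      lex[[i]] <- entries
    }
    n_amb <- round(cfg$ambiguity_rate * cfg$lexicon_size)
    if (n_amb > 0L && k > 1L) {
      for (i in seq_len(k)) {
        j <- if (i == k) 1L else i + 1L
        lex[[j]][seq_len(n_amb)] <- lex[[i]][cfg$lexicon_size -
                                               seq_len(n_amb) + 1L]
      }
    }
    lex
  })
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the configuration.  Every planted entity's characters
#' come from its lexicon entry; background characters are drawn from a pool
#' disjoint from the entity-character pool, so in the easy regime no
#' background run ever forms a lexicon entry.  In the hard regime ambiguous
#' entries occur under two types and a type-specific cue character is placed
#' immediately before each planted entity.
#'
#' @param cfg a [synth_config()].
#' @return list with \code{corpus} (an annotated corpus) and \code{truth}
#'   (list with \code{spans}, a data frame of planted spans, and \code{f},
#'   the per-catalog-type planted span counts).
#' @export
synth_generate <- function(cfg) {
  catalog <- entity_catalog()
  lex <- .synth_lexicons(cfg)
  ab <- .synth_alphabet(cfg)
  cues <- ab$cue
  names(cues) <- cfg$active_types
  k <- length(cfg$active_types)
  n_sent <- cfg$n_chapters * cfg$paragraphs_per_chapter *
    cfg$sentences_per_paragraph

  # phase 1: structural draws only, so corpora that differ only in type
  # weights share the same hierarchy and sentence lengths
  structural <- with_seed(cfg$text_seed, {
    list(len = sample(cfg$sentence_len[1]:cfg$sentence_len[2], n_sent,
                      replace = TRUE),
         k_ent = stats::rbinom(n_sent, cfg$max_entities,
                               cfg$entity_density))
  })

  spans <- list()
  f <- integer(nrow(catalog))
  names(f) <- catalog$code
  si <- 0L
  corpus <- with_seed(cfg$text_seed + 1L, {
    chapters_out <- vector("list", cfg$n_chapters)
    for (ci in seq_len(cfg$n_chapters)) {
      paras <- vector("list", cfg$paragraphs_per_chapter)
      for (pi in seq_len(cfg$paragraphs_per_chapter)) {
        sents <- vector("list", cfg$sentences_per_paragraph)
        for (qi in seq_len(cfg$sentences_per_paragraph)) {
          si <- si + 1L
          L <- structural$len[si]
          chars <- sample(ab$background, L, replace = TRUE)
          tags <- rep("O", L)
          n_e <- structural$k_ent[si]
          cursor <- 1L
          planted <- 0L
          while (planted < n_e) {
            ti <- sample.int(k, 1L, prob = cfg$type_weights)
            code <- cfg$active_types[ti]
            room <- L - cursor + 1L
            cue_len <- as.integer(cfg$ambiguity_rate > 0)
            fits <- lex[[ti]][nchar(lex[[ti]]) + cue_len <= room]
            if (!length(fits)) break
            entry <- sample(fits, 1L)
            ec <- strsplit(entry, "", fixed = TRUE)[[1]]
            need <- length(ec) + cue_len
            gap <- if (room - need > 0L) sample.int(room - need + 1L, 1L) - 1L
            else 0L
            at <- cursor + gap
            if (cfg$ambiguity_rate > 0) {
              chars[at] <- cues[[code]] # left-context cue
              at <- at + 1L
            }
            idx <- at:(at + length(ec) - 1L)
            chars[idx] <- ec
            tags[idx] <- c(paste0("B-", code),
                           rep(paste0("I-", code), length(ec) - 1L))
            f[code] <- f[code] + 1L
            spans[[length(spans) + 1L]] <- data.frame(
              chapter = ci, paragraph = pi, sentence = qi,
              start = idx[1], end = idx[length(idx)] + 1L, code = code,
              stringsAsFactors = FALSE)
            cursor <- idx[length(idx)] + 2L # at least one O between spans
            planted <- planted + 1L
          }
          sents[[qi]] <- new_sentence(chars, tags)
        }
        paras[[pi]] <- sents
      }
      chapters_out[[ci]] <- paras
    }
    new_corpus(list(new_document(cfg$doc_type, chapters_out)))
  })

  spans_df <- if (length(spans)) do.call(rbind, spans) else
    data.frame(chapter = integer(), paragraph = integer(),
               sentence = integer(), start = integer(), end = integer(),
               code = character(), stringsAsFactors = FALSE)
  list(corpus = corpus, truth = list(spans = spans_df, f = f))
}

#' Generate two corpora differing only in entity-type skew
#'
#' Both corpora share the configuration and structural seed (hierarchy and
#' sentence lengths) and differ only in the type-frequency weights, which
#' makes them a matched pair for studying the entity-distribution seed.
#'
#' @param cfg a [synth_config()].
#' @param weights1,weights2 two weight vectors over \code{cfg$active_types}.
#' @return list of two \code{synth_generate} results.
#' @export
synth_skewed_pair <- function(cfg, weights1, weights2) {
  if (isTRUE(all.equal(weights1, weights2))) {
    stop("weight vectors must differ")
  }
  c1 <- cfg; c1$type_weights <- weights1 / sum(weights1)
  c2 <- cfg; c2$type_weights <- weights2 / sum(weights2)
  list(synth_generate(c1), synth_generate(c2))
}

#' Subsample a corpus at sentence level
#'
#' Samples sentences without replacement, preserving the document/chapter/
#' paragraph hierarchy and dropping units that become empty.  Used to study
#' behaviour as the training corpus shrinks.
#'
#' @param corpus an annotated corpus.
#' @param fraction in (0, 1]; \code{round(fraction * n)} sentences are kept.
#' @param rng_seed integer seed.
#' @return an annotated corpus.
#' @export
synth_subsample <- function(corpus, fraction, rng_seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(corpus)
  n <- length(corpus_sentences(corpus))
  keep_n <- round(fraction * n)
  keep <- sort(with_seed(rng_seed, sample.int(n, keep_n)))
  si <- 0L
  docs <- lapply(corpus, function(doc) {
    chapters <- lapply(doc$chapters, function(ch) {
      paras <- lapply(ch, function(pa) {
        out <- list()
        for (se in pa) {
          si <<- si + 1L
          if (si %in% keep) out[[length(out) + 1L]] <- se
        }
        out
      })
      paras[lengths(paras) > 0L]
    })
    chapters <- chapters[lengths(chapters) > 0L]
    new_document(doc$doc_type, chapters)
  })
  new_corpus(docs[vapply(docs, function(d) length(d$chapters) > 0L,
                         logical(1))])
}
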