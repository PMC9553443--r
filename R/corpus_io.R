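# Hierarchical annotated-corpus data model and the two-column BIO file
# dialect.
#
# A corpus is a list of documents.  A document is
#   list(doc_type = <chr>, chapters = list(paragraphs)),
#   paragraph = list(sentences), sentence = list(chars = <chr vec>,
#   tags = <chr vec>).
# File dialect: "<char>\t<tag>" lines; one blank line ends a sentence, two
# consecutive blank lines end a paragraph; a line "-DOCSTART-" ends a
# chapter; a line "-DOCSTART- type=<doc_type>" starts a new document.

new_sentence <- function(chars, tags) list(chars = chars, tags = tags)

new_document <- function(doc_type = "comprehensive", chapters = list()) {
  structure(list(doc_type = doc_type, chapters = chapters),
            class = "ner_document")
}

new_corpus <- function(docs) structure(docs, class = "ner_corpus")

#' @export
print.ner_corpus <- function(x, ...) {
  ns <- corpus_sentences(x)
  cat("Annotated corpus:", length(x), "document(s),", length(ns),
      "sentence(s),", sum(lengths(lapply(ns, `[[`, "chars"))),
      "characters\n")
  invisible(x)
}

# flat list of sentences of a corpus (order: document, chapter, paragraph)
corpus_sentences <- function(corpus) {
  out <- list()
  for (doc in corpus) {
    for (ch in doc$chapters) {
      for (pa in ch) out <- c(out, pa)
    }
  }
  out
}

# flat character/tag streams
corpus_chars <- function(corpus) {
  unlist(lapply(corpus_sentences(corpus), `[[`, "chars"), use.names = FALSE)
}
corpus_tags <- function(corpus) {
  unlist(lapply(corpus_sentences(corpus), `[[`, "tags"), use.names = FALSE)
}

# validate BIO transitions in one sentence; returns NULL or the offending
# position
bio_violation <- function(tags) {
  prev <- "O"
  prev_code <- ""
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (startsWith(tg, "I-")) {
      code <- substring(tg, 3L)
      ok <- (startsWith(prev, "B-") || startsWith(prev, "I-")) &&
        prev_code == code
      if (!ok) return(i)
    }
    prev <- tg
    prev_code <- if (tg == "O") "" else substring(tg, 3L)
  }
  NULL
}

#' Read a two-column BIO annotation file
#'
#' Parses a UTF-8 file of \code{"<char>\\t<tag>"} lines into the hierarchical
#' document model.  One blank line ends a sentence; two consecutive blank
#' lines end a paragraph; a line \code{-DOCSTART-} ends a chapter; a line
#' \code{-DOCSTART- type=<doc_type>} additionally starts a new document of
#' the given type.
#'
#' @param path input file path.
#' @param catalog an [entity_catalog()]; every non-\code{O} tag must name one
#'   of its type codes.
#' @param doc_type document type assigned to content before the first
#'   typed \code{-DOCSTART-} marker.
#' @param validate check BIO transition validity (gold data); an
#'   \code{I-X} tag not preceded by \code{B-X}/\code{I-X} is an error.
#' @return an annotated corpus (class \code{ner_corpus}).
#' @export
read_conll <- function(path, catalog = entity_catalog(),
                       doc_type = "comprehensive", validate = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  docs <- list()
  chapters <- list()
  paragraphs <- list()
  sentences <- list()
  chars <- character()
  tags <- character()
  cur_type <- doc_type
  n_sent_total <- 0L
  blank_run <- 0L

  flush_sentence <- function(lineno) {
    if (!length(chars)) return(invisible(NULL))
    if (validate) {
      vi <- bio_violation(tags)
      if (!is.null(vi)) {
        stop("invalid BIO transition at sentence position ", vi,
             " (near line ", lineno, "): ", tags[vi])
      }
    }
    sentences[[length(sentences) + 1L]] <<- new_sentence(chars, tags)
    chars <<- character(); tags <<- character()
    n_sent_total <<- n_sent_total + 1L
    invisible(NULL)
  }
  flush_paragraph <- function() {
    if (length(sentences)) {
      paragraphs[[length(paragraphs) + 1L]] <<- sentences
      sentences <<- list()
    }
    invisible(NULL)
  }
  flush_chapter <- function() {
    flush_paragraph()
    if (length(paragraphs)) {
      chapters[[length(chapters) + 1L]] <<- paragraphs
      paragraphs <<- list()
    }
    invisible(NULL)
  }
  flush_document <- function() {
    flush_chapter()
    if (length(chapters)) {
      docs[[length(docs) + 1L]] <<- new_document(cur_type, chapters)
      chapters <<- list()
    }
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") {
      blank_run <- blank_run + 1L
      if (blank_run == 1L) flush_sentence(i)
      if (blank_run == 2L) flush_paragraph()
      next
    }
    if (startsWith(ln, "-DOCSTART-")) {
      blank_run <- 0L
      flush_sentence(i)
      m <- regmatches(ln, regexec("type=(\\S+)", ln))[[1]]
      if (length(m) == 2L) {
        flush_document()
        cur_type <- m[2]
      } else {
        flush_chapter()
      }
      next
    }
    blank_run <- 0L
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || nchar(parts[1]) != 1L) {
      stop("malformed line ", i, ": ", ln)
    }
    parse_tag(parts[2], catalog) # raises on unknown tag
    chars <- c(chars, parts[1])
    tags <- c(tags, parts[2])
  }
  flush_sentence(length(lines))
  flush_document()
  new_corpus(docs)
}

#' Write a corpus as a two-column BIO annotation file
#'
#' Inverse of [read_conll()]: \code{read_conll(write_conll(x))} reproduces
#' \code{x} byte-stably.
#'
#' @param corpus an annotated corpus.
#' @param path output file path.
#' @export
write_conll <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  put <- function(s) writeLines(s, con, useBytes = TRUE)
  for (doc in corpus) {
    if (!length(doc$chapters)) next # empty documents leave no trace
    put(enc2utf8(paste0("-DOCSTART- type=", doc$doc_type)))
    first_chap <- TRUE
    for (ch in doc$chapters) {
      if (!first_chap) put("-DOCSTART-")
      first_chap <- FALSE
      first_par <- TRUE
      for (pa in ch) {
        if (!first_par) put("") # second blank: paragraph break
        first_par <- FALSE
        for (se in pa) {
          put(enc2utf8(paste(se$chars, se$tags, sep = "\t")))
          put("") # sentence break
        }
      }
    }
  }
  invisible(path)
}

#' Build a character vocabulary from a corpus
#'
#' Characters with frequency at least \code{min_count} receive ids in order
#' of decreasing frequency (ties broken by code point); id 0 is reserved for
#' padding and id 1 for unknown characters.  The mapping is deterministic
#' given the corpus.
#'
#' @param corpus an annotated corpus.
#' @param min_count minimum frequency for a character to get its own id.
#' @return object of class \code{ner_vocab}: list with \code{char_to_id}
#'   (named integer vector, 0-based ids), \code{id_to_char}, \code{size}.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  chars <- corpus_chars(corpus)
  if (!length(chars)) stop("empty corpus")
  tab <- table(chars)
  keep <- names(tab)[tab >= min_count]
  ord <- order(-as.numeric(tab[keep]), keep)
  keep <- keep[ord]
  id_to_char <- c("<pad>", "<unk>", keep)
  ids <- seq_along(id_to_char) - 1L
  names(ids) <- id_to_char
  structure(list(char_to_id = ids, id_to_char = id_to_char,
                 size = length(id_to_char)),
            class = "ner_vocab")
}

#' @export
print.ner_vocab <- function(x, ...) {
  cat("Character vocabulary: size", x$size,
      "(ids 0 = <pad>, 1 = <unk>)\n")
  invisible(x)
}

#' Encode a sentence as id sequence and mask
#'
#' @param chars character vector (single code points).
#' @param vocab a vocabulary from [build_vocab()].
#' @param length pad/extend to this length (default: no padding).
#' @return list with \code{ids} (0-based integer ids; unknown characters map
#'   to id 1, padding to id 0) and \code{mask} (logical, \code{TRUE} at real
#'   positions).
#' @export
encode_sentence <- function(chars, vocab, length = NULL) {
  if (!length(chars)) stop("empty sentence")
  ids <- unname(vocab$char_to_id[chars])
  ids[is.na(ids)] <- 1L
  mask <- rep(TRUE, base::length(ids))
  if (!is.null(length) && length > base::length(ids)) {
    pad <- length - base::length(ids)
    ids <- c(ids, rep(0L, pad))
    mask <- c(mask, rep(FALSE, pad))
  }
  list(ids = as.integer(ids), mask = mask)
}
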