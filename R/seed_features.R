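# The "seed of entity distribution features": a corpus-type prior built from
# the empirical frequency of each entity type.  Each of the 19 types gets an
# initial vector v_i (type-independent); the per-type span frequencies f_i of
# an annotated corpus give probabilities p_i = f_i / sum(f), and the seed is
# the splice [p_1 v_1 || p_2 v_2 || ... || p_19 v_19].

#' Initial entity-type vectors
#'
#' Generates one initial vector per catalog type, independent of corpus
#' type.  By default the vectors are seeded random unit vectors; externally
#' trained embeddings can be supplied instead via \code{vectors}.
#'
#' @param catalog an [entity_catalog()].
#' @param d_emb embedding dimension of each vector.
#' @param rng_seed integer seed; the vectors are a deterministic function of
#'   it.
#' @param unit normalise each vector to unit Euclidean norm (default TRUE).
#' @param vectors optional user-supplied matrix (\code{n_types x d_emb})
#'   overriding the random draw.
#' @return matrix with one row per catalog type.
#' @export
init_entity_vectors <- function(catalog, d_emb = 16L, rng_seed = 1L,
                                unit = TRUE, vectors = NULL) {
  n <- nrow(catalog)
  if (!is.null(vectors)) {
    stopifnot(nrow(vectors) == n, ncol(vectors) == d_emb)
    V <- vectors
  } else {
    V <- with_seed(rng_seed, matrix(stats::rnorm(n * d_emb), n, d_emb))
  }
  if (unit) V <- V / sqrt(rowSums(V * V))
  rownames(V) <- catalog$code
  V
}

#' Count entity spans per type
#'
#' \code{f_i} is the number of gold entity spans of type \code{i} in the
#' corpus: each \code{B-X} tag starts one span.
#'
#' @param corpus an annotated corpus with gold BIO tags.
#' @param catalog an [entity_catalog()].
#' @return named integer vector of length \code{nrow(catalog)}, in catalog
#'   order.
#' @export
count_frequencies <- function(corpus, catalog = entity_catalog()) {
  f <- integer(nrow(catalog))
  names(f) <- catalog$code
  tags <- corpus_tags(corpus)
  if (length(tags)) {
    b <- tags[startsWith(tags, "B-")]
    if (length(b)) {
      tb <- table(substring(b, 3L))
      hit <- intersect(names(tb), names(f))
      f[hit] <- as.integer(tb[hit])
    }
  }
  f
}

#' Entity-type probability distribution
#'
#' @param f non-negative frequency vector (one entry per type).
#' @return probabilities \code{p_i = f_i / sum(f)}; errors if all
#'   frequencies are zero.
#' @export
entity_probabilities <- function(f) {
  if (any(f < 0)) stop("negative frequency")
  s <- sum(f)
  if (s == 0) stop("no entities in corpus: all frequencies zero")
  f / s
}

#' Build the entity-distribution seed vector
#'
#' Concatenates the probability-weighted initial vectors:
#' \eqn{[p_1 v_1 \| p_2 v_2 \| \ldots \| p_{19} v_{19}]}.  Block \code{i} of
#' the result equals \code{p[i] * V[i, ]}; the seed has length
#' \code{n_types * d_emb} and is a deterministic function of the vector seed
#' and the corpus frequencies.  Scaling all frequencies by a constant leaves
#' the seed unchanged.
#'
#' @param catalog an [entity_catalog()].
#' @param f per-type span frequencies (see [count_frequencies()]).
#' @param V initial vectors from [init_entity_vectors()].
#' @param mode \code{"distribution"} (default) for the probability-weighted
#'   seed, or \code{"random"} for an ablation seed of fresh random blocks of
#'   the same overall scale.
#' @param rng_seed seed for the \code{"random"} mode blocks.
#' @return object of class \code{seed_vector}: numeric vector with
#'   attributes \code{p}, \code{d_emb}, \code{mode}.
#' @export
build_seed <- function(catalog, f, V, mode = c("distribution", "random"),
                       rng_seed = 1L) {
  mode <- match.arg(mode)
  p <- entity_probabilities(f)
  d_emb <- ncol(V)
  if (mode == "distribution") {
    blocks <- V * p # row-wise scaling
  } else {
    blocks <- with_seed(rng_seed + 77L,
                        matrix(stats::rnorm(length(V), 0, mean(p)),
                               nrow(V), d_emb))
  }
  s <- as.numeric(t(blocks))
  structure(s, p = p, d_emb = d_emb, mode = mode, class = "seed_vector")
}

#' @export
print.seed_vector <- function(x, ...) {
  cat("Entity-distribution seed: length", length(x),
      sprintf("(%d types x d_emb %d), mode '%s'\n",
              length(attr(x, "p")), attr(x, "d_emb"), attr(x, "mode")))
  invisible(x)
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
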