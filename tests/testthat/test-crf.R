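# CRF decoding, span extraction and entity-level evaluation.

test_that("viterbi with uniform transitions is the emission argmax", {
  set.seed(1)
  em <- rand_mat(6, 5)
  par0 <- list(trans = matrix(0, 5, 5), start = rep(0, 5),
               stop = rep(0, 5))
  expect_identical(viterbi_decode(em, par0),
                   apply(em, 1, which.max))
  em1 <- rand_mat(1, 5)
  expect_identical(viterbi_decode(em1, par0), which.max(em1))
})

test_that("viterbi matches exhaustive enumeration on random instances", {
  set.seed(2)
  for (i in 1:40) {
    Tn <- sample(1:5, 1); n <- sample(2:7, 1)
    em <- rand_mat(Tn, n)
    par <- list(trans = rand_mat(n, n), start = rnorm(n), stop = rnorm(n))
    expect_identical(viterbi_decode(em, par),
                     oracle_viterbi(em, par$trans, par$start, par$stop))
  }
})

test_that("viterbi ties break toward the lowest tag index", {
  par0 <- list(trans = matrix(0, 4, 4), start = rep(0, 4),
               stop = rep(0, 4))
  expect_identical(viterbi_decode(matrix(0, 3, 4), par0), rep(1L, 3))
})

test_that("crf_fit reproduces a constant tag sequence and improves NLL", {
  tags <- nergan:::tag_set(entity_catalog())
  n <- length(tags)
  set.seed(3)
  # one training sequence, constant gold tag (a B- tag, so the sequence is
  # BIO-legal under the hard mask), weak emissions
  b_zz <- which(tags == "B-ZZ")
  em <- list(matrix(0, 6, n))
  gold <- list(rep(b_zz, 6))
  crf <- crf_fit(em, gold, tags, iters = 30L, lr = 0.5)
  expect_identical(viterbi_decode(em[[1]], crf), rep(b_zz, 6))
  expect_lt(crf$nll[30], crf$nll[1])
  expect_true(all(diff(crf$nll) < 1e-3)) # essentially non-increasing
})

test_that("hard mask forbids impossible BIO transitions in every decode", {
  tags <- nergan:::tag_set(entity_catalog())
  n <- length(tags)
  set.seed(4)
  em <- lapply(1:6, function(i) rand_mat(sample(2:6, 1), n) * 3)
  gold <- lapply(em, function(m) rep(1L, nrow(m)))
  crf <- crf_fit(em, gold, tags, iters = 5L, lr = 0.2,
                 mask_illegal = TRUE)
  ok_prev <- function(prev, tag) {
    if (!startsWith(tag, "I-")) return(TRUE)
    code <- substring(tag, 3)
    prev %in% paste0(c("B-", "I-"), code)
  }
  for (i in 1:30) {
    m <- rand_mat(sample(1:7, 1), n) * 4
    path <- tags[viterbi_decode(m, crf)]
    expect_false(startsWith(path[1], "I-"))
    if (length(path) > 1) {
      for (t in 2:length(path)) {
        expect_true(ok_prev(path[t - 1], path[t]))
      }
    }
  }
})

test_that("extract_entities handles runs, stray I tags and both policies", {
  expect_identical(extract_entities(c("B-ZZ", "I-ZZ", "O")),
                   data.frame(code = "ZZ", start = 0L, end = 2L,
                              stringsAsFactors = FALSE))
  expect_identical(nrow(extract_entities(c("O", "O", "O"))), 0L)
  rep_ <- extract_entities(c("I-ZZ", "I-ZZ"))
  expect_identical(rep_, data.frame(code = "ZZ", start = 0L, end = 2L,
                                    stringsAsFactors = FALSE))
  expect_identical(nrow(extract_entities(c("I-ZZ", "I-ZZ"),
                                         stray = "drop")), 0L)
  # type switch inside a run starts a new span
  two <- extract_entities(c("B-ZY", "I-MX"))
  expect_identical(two$code, c("ZY", "MX"))
})

test_that("span extraction inverts tag construction on valid sequences", {
  set.seed(5)
  codes <- entity_catalog()$code
  for (i in 1:25) {
    L <- sample(4:12, 1)
    tags <- rep("O", L)
    pos <- 1L
    while (pos <= L - 1L) {
      if (runif(1) < 0.4) {
        len <- sample(1:min(3, L - pos + 1L), 1)
        cd <- sample(codes, 1)
        tags[pos:(pos + len - 1L)] <- c(paste0("B-", cd),
                                        rep(paste0("I-", cd), len - 1L))
        pos <- pos + len + 1L
      } else pos <- pos + 1L
    }
    sp <- extract_entities(tags)
    rebuilt <- rep("O", L)
    for (r in seq_len(nrow(sp))) {
      idx <- (sp$start[r] + 1L):sp$end[r]
      rebuilt[idx] <- c(paste0("B-", sp$code[r]),
                        rep(paste0("I-", sp$code[r]), length(idx) - 1L))
    }
    expect_identical(rebuilt, tags)
  }
})

test_that("evaluation formulas and the span-set oracle agree", {
  perfect <- list(c("B-ZZ", "I-ZZ", "O"), c("O", "B-ZY", "O"))
  m <- evaluate_ner(perfect, perfect)
  expect_equal(unname(m$overall), c(100, 100, 100))

  pred <- list(c("B-ZZ", "I-ZZ", "O", "B-ZY", "O"))
  gold <- list(c("B-ZZ", "I-ZZ", "O", "O", "B-ZY"))
  m2 <- evaluate_ner(pred, gold, per_type = FALSE)
  expect_equal(unname(m2$overall), c(50, 50, 50))

  set.seed(6)
  codes <- c("ZZ", "ZY", "MX")
  rand_tags <- function(L = sample(3:10, 1)) {
    tags <- rep("O", L)
    for (s in seq_len(sample(0:2, 1))) {
      at <- sample(L, 1)
      tags[at] <- paste0("B-", sample(codes, 1))
    }
    tags
  }
  for (i in 1:20) {
    pr <- replicate(4, rand_tags(), simplify = FALSE)
    gl <- lapply(pr, function(tg) if (runif(1) < 0.5) tg else
      rand_tags(length(tg)))
    m3 <- evaluate_ner(pr, gl, per_type = FALSE)
    expect_equal(unname(m3$overall), unname(oracle_prf(pr, gl)),
                 tolerance = 1e-10)
  }
  expect_error(evaluate_ner(list(c("O")), list(c("O", "O"))), "lengths")
  expect_error(evaluate_ner(list(), list(c("O"))), "counts")
})

test_that("adding a correct span never decreases recall", {
  gold <- list(c("B-ZZ", "O", "B-ZY", "O"))
  pred1 <- list(c("B-ZZ", "O", "O", "O"))
  pred2 <- list(c("B-ZZ", "O", "B-ZY", "O"))
  r1 <- evaluate_ner(pred1, gold, per_type = FALSE)$overall["R"]
  r2 <- evaluate_ner(pred2, gold, per_type = FALSE)$overall["R"]
  expect_gte(r2, r1)
})
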