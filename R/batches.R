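# Minibatch construction.  A batch groups whole paragraphs (so the
# paragraph- and chapter-granularity encoders amortise over their
# sentences) until it holds at least `batch_size` sentences.  All gather /
# convolution / interpolation index structures are precomputed here and
# reused every epoch; only the batch visiting order is reshuffled.
#
# Layouts are time-major: row (t-1)*B + b is position t of sequence b.

# linear-interpolation indices resampling each sequence (true length
# lens[b]) onto L uniform positions; returns i1, i2 (rows, 0 = zero row), w
.interp_index <- function(lens, B, L, Tmax) {
  i1 <- integer(B * L); i2 <- integer(B * L); w <- numeric(B * L)
  for (b in seq_len(B)) {
    Tb <- lens[b]
    rows <- b + B * (seq_len(L) - 1L)
    if (Tb == 0L) { w[rows] <- 1; next }
    src <- (seq_len(L) - 0.5) * Tb / L + 0.5
    i <- floor(src)
    fr <- src - i
    a1 <- pmin(pmax(i, 1L), Tb)
    a2 <- pmin(pmax(i + 1L), Tb)
    i1[rows] <- b + B * (a1 - 1L)
    i2[rows] <- b + B * (a2 - 1L)
    w[rows] <- 1 - fr
  }
  list(i1 = i1, i2 = i2, w = w)
}

# inverse: map sentence positions onto an L-length decoder top layout
.gather_back_index <- function(lens, B, L) {
  Tmax <- max(lens)
  i1 <- integer(B * Tmax); i2 <- integer(B * Tmax); w <- numeric(B * Tmax)
  for (b in seq_len(B)) {
    Tb <- lens[b]
    if (Tb == 0L) next
    rows <- b + B * (seq_len(Tb) - 1L)
    src <- (seq_len(Tb) - 0.5) * L / Tb + 0.5
    i <- floor(src)
    fr <- src - i
    a1 <- pmin(pmax(i, 1L), L)
    a2 <- pmin(pmax(i + 1L), L)
    i1[rows] <- b + B * (a1 - 1L)
    i2[rows] <- b + B * (a2 - 1L)
    w[rows] <- 1 - fr
  }
  list(i1 = i1, i2 = i2, w = w)
}

# flatten a corpus into sentence records with paragraph/chapter coordinates
.sentence_table <- function(corpus) {
  recs <- list()
  pid <- 0L; cid <- 0L
  for (di in seq_along(corpus)) {
    doc <- corpus[[di]]
    for (ch in doc$chapters) {
      cid <- cid + 1L
      for (pa in ch) {
        pid <- pid + 1L
        for (se in pa) {
          recs[[length(recs) + 1L]] <-
            list(chars = se$chars, tags = se$tags, pid = pid, cid = cid)
        }
      }
    }
  }
  recs
}

make_batches <- function(corpus, vocab, catalog, cfg) {
  tags_all <- tag_set(catalog)
  recs <- .sentence_table(corpus)
  if (!length(recs)) stop("corpus has no sentences")
  pids <- vapply(recs, `[[`, integer(1), "pid")
  groups <- split(seq_along(recs), pids)
  batches <- list()
  cur <- integer()
  for (g in groups) {
    cur <- c(cur, g)
    if (length(cur) >= cfg$batch_size) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer()
    }
  }
  if (length(cur)) {
    if (length(batches)) {
      batches[[length(batches)]] <- c(batches[[length(batches)]], cur)
    } else {
      batches[[1L]] <- cur
    }
  }
  lapply(batches, function(sel) {
    .build_batch(recs[sel], vocab, tags_all, cfg)
  })
}

.build_batch <- function(srecs, vocab, tags_all, cfg) {
  B <- length(srecs)
  lens <- vapply(srecs, function(r) length(r$chars), integer(1))
  Tmax <- max(lens)
  ids <- integer(B * Tmax)
  gold <- integer(B * Tmax)
  mask <- numeric(B * Tmax)
  for (b in seq_len(B)) {
    enc <- encode_sentence(srecs[[b]]$chars, vocab)
    rows <- b + B * (seq_len(lens[b]) - 1L)
    ids[rows] <- enc$ids
    gold[rows] <- match(srecs[[b]]$tags, tags_all)
    mask[rows] <- 1
  }

  # paragraph layout: concatenated characters of each distinct paragraph
  up <- unique(vapply(srecs, `[[`, integer(1), "pid"))
  P <- length(up)
  plen <- integer(P)
  off <- integer(B) # char offset of each sentence inside its paragraph
  pidx <- integer(B)
  for (b in seq_len(B)) {
    p <- match(srecs[[b]]$pid, up)
    pidx[b] <- p
    off[b] <- plen[p]
    plen[p] <- plen[p] + lens[b]
  }
  Tp <- max(plen)
  ids_p <- integer(P * Tp)
  for (b in seq_len(B)) {
    enc <- encode_sentence(srecs[[b]]$chars, vocab)
    rows <- pidx[b] + P * (off[b] + seq_len(lens[b]) - 1L)
    ids_p[rows] <- enc$ids
  }
  mask_p <- numeric(P * Tp)
  for (p in seq_len(P)) {
    mask_p[p + P * (seq_len(plen[p]) - 1L)] <- 1
  }
  # sentence-layout row -> paragraph-layout row
  map_sp <- integer(B * Tmax)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(lens[b]) - 1L)
    map_sp[rows] <- pidx[b] + P * (off[b] + seq_len(lens[b]) - 1L)
  }

  # chapter layout: concatenated characters of each distinct chapter
  uc <- unique(vapply(srecs, `[[`, integer(1), "cid"))
  Bc <- length(uc)
  clen <- integer(Bc)
  coff <- integer(B)
  cidx <- integer(B)
  for (b in seq_len(B)) {
    cc <- match(srecs[[b]]$cid, uc)
    cidx[b] <- cc
    coff[b] <- clen[cc]
    clen[cc] <- clen[cc] + lens[b]
  }
  Tc <- max(clen)
  ids_c <- integer(Bc * Tc)
  for (b in seq_len(B)) {
    rows <- cidx[b] + Bc * (coff[b] + seq_len(lens[b]) - 1L)
    enc <- encode_sentence(srecs[[b]]$chars, vocab)
    ids_c[rows] <- enc$ids
  }
  # per-row chapter index for broadcasting h_a (0 at padded rows)
  chap_row <- integer(B * Tmax)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(lens[b]) - 1L)
    chap_row[rows] <- cidx[b]
  }

  # decoder-level interpolation and convolution caches
  n_lev <- 6L
  lev_len <- cfg$seed_len %/% 2L^(n_lev - seq_len(n_lev)) # 4,8,...,128
  interp <- lapply(lev_len, function(L) .interp_index(lens, B, L, Tmax))
  conv_idx <- lapply(lev_len, function(L) conv_index(B, L, 3L))
  back <- .gather_back_index(lens, B, cfg$seed_len)
  conv_idx_sent <- conv_index(B, Tmax, 3L)
  conv_idx_chap <- conv_index(Bc, Tc, 3L)
  rows_s <- lapply(seq_len(B), function(b) b + B * (seq_len(lens[b]) - 1L))
  rows_p <- lapply(seq_len(P), function(p) p + P * (seq_len(plen[p]) - 1L))

  list(B = B, Tmax = Tmax, lens = lens, ids = ids, gold = gold,
       mask = mask,
       P = P, Tp = Tp, plen = plen, ids_p = ids_p, mask_p = mask_p,
       map_sp = map_sp,
       Bc = Bc, Tc = Tc, clen = clen, ids_c = ids_c, chap_row = chap_row,
       lev_len = lev_len, interp = interp, conv_idx = conv_idx,
       back = back, conv_idx_sent = conv_idx_sent,
       conv_idx_chap = conv_idx_chap, rows_s = rows_s, rows_p = rows_p)
}
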