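# Linear-chain CRF over the 39-tag BIO space.  Emissions are the generator's
# label score sequences; only the transition structure (plus start/stop
# scores) is estimated, by maximising the CRF log-likelihood with emissions
# held fixed.  Decoding is exact Viterbi with first-index tie-breaking.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# illegal BIO transition mask for a tag set in tag_set() order:
# start -> I-X, O -> I-X, and {B,I}-X -> I-Y are structurally impossible
illegal_mask <- function(tags) {
  n <- length(tags)
  M <- matrix(FALSE, n, n, dimnames = list(tags, tags))
  codes <- ifelse(tags == "O", "", substring(tags, 3L))
  is_i <- startsWith(tags, "I-")
  for (j in which(is_i)) {
    ok_prev <- codes == codes[j] & tags != "O"
    M[!ok_prev, j] <- TRUE
  }
  start_bad <- is_i
  list(trans = M, start = start_bad)
}

#' Viterbi decoding of a label score sequence
#'
#' Finds the maximum-scoring tag path under per-position emission scores
#' plus transition, start and stop scores.  Ties are broken toward the
#' lowest tag index at every step, so the decode is fully deterministic.
#'
#' @param emissions \code{T x n_tags} matrix of real-valued label scores.
#' @param params CRF parameters: list with \code{trans}
#'   (\code{n_tags x n_tags}), \code{start}, \code{stop} (length
#'   \code{n_tags}).  Uniform/zero parameters reduce the decode to the
#'   per-position emission argmax.
#' @return integer vector of tag indices (1-based), length \code{nrow(emissions)}.
#' @export
viterbi_decode <- function(emissions, params) {
  Tn <- nrow(emissions)
  n <- ncol(emissions)
  delta <- params$start + emissions[1L, ]
  back <- matrix(0L, Tn, n)
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      M <- delta + params$trans # n x n: prev i -> next j
      am <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(am, seq_len(n))] + emissions[t, ]
      back[t, ] <- am
    }
  }
  fin <- delta + params$stop
  path <- integer(Tn)
  path[Tn] <- which.max(fin)
  if (Tn > 1L) {
    for (t in Tn:2L) path[t - 1L] <- back[t, path[t]]
  }
  path
}

# vectorised log-sum-exp over columns / rows of a matrix
.lse_cols <- function(M) {
  mx <- as.numeric(do.call(pmax, asplit(M, 1L)))
  mx + log(colSums(exp(M - rep(mx, each = nrow(M)))))
}
.lse_rows <- function(M) {
  mx <- as.numeric(do.call(pmax, asplit(M, 2L)))
  mx + log(rowSums(exp(M - mx)))
}

# negative log-likelihood and gradients for one sequence
.crf_seq_grad <- function(em, gold, trans, start, stop) {
  Tn <- nrow(em)
  n <- ncol(em)
  alpha <- matrix(0, Tn, n)
  alpha[1L, ] <- start + em[1L, ]
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      alpha[t, ] <- .lse_cols(alpha[t - 1L, ] + trans) + em[t, ]
    }
  }
  logZ <- logsumexp(alpha[Tn, ] + stop)
  beta <- matrix(0, Tn, n)
  beta[Tn, ] <- stop
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      beta[t, ] <- .lse_rows(trans + rep(em[t + 1L, ] + beta[t + 1L, ],
                                         each = n))
    }
  }
  # expected minus observed sufficient statistics
  g_trans <- matrix(0, n, n)
  if (Tn > 1L) {
    for (t in 2L:Tn) {
      lp <- outer(alpha[t - 1L, ], em[t, ] + beta[t, ], "+") + trans - logZ
      g_trans <- g_trans + exp(lp)
      g_trans[gold[t - 1L], gold[t]] <- g_trans[gold[t - 1L], gold[t]] - 1
    }
  }
  post1 <- exp(alpha[1L, ] + beta[1L, ] - logZ)
  g_start <- post1
  g_start[gold[1L]] <- g_start[gold[1L]] - 1
  postT <- exp(alpha[Tn, ] + stop - logZ)
  g_stop <- postT
  g_stop[gold[Tn]] <- g_stop[gold[Tn]] - 1
  score <- start[gold[1L]] + sum(em[cbind(seq_len(Tn), gold)]) +
    stop[gold[Tn]] +
    if (Tn > 1L) sum(trans[cbind(gold[-Tn], gold[-1L])]) else 0
  list(nll = logZ - score, g_trans = g_trans, g_start = g_start,
       g_stop = g_stop)
}

#' Fit CRF transition parameters on fixed emission scores
#'
#' Estimates the transition/start/stop scores by gradient-based maximisation
#' of the conditional log-likelihood of the gold tag sequences given the
#' emission scores (Adam, emissions fixed).  Structurally impossible BIO
#' transitions can be hard-masked to a large negative score.
#'
#' @param emissions list of \code{T x n_tags} score matrices.
#' @param gold list of integer tag-index vectors aligned with
#'   \code{emissions}.
#' @param tags character vector naming the tag space (see internal
#'   \code{tag_set}); its length fixes \code{n_tags}.
#' @param iters optimisation steps.
#' @param lr Adam learning rate.
#' @param mask_illegal hard-mask impossible BIO transitions (default TRUE).
#' @return object of class \code{crf_params}: list with \code{trans},
#'   \code{start}, \code{stop}, \code{tags}, \code{nll} (per-iteration mean
#'   negative log-likelihood).
#' @export
crf_fit <- function(emissions, gold, tags, iters = 40L, lr = 0.2,
                    mask_illegal = TRUE) {
  if (!length(emissions)) stop("empty input")
  n <- length(tags)
  trans <- matrix(0, n, n)
  start <- numeric(n)
  stp <- numeric(n)
  msk <- illegal_mask(tags)
  NEG <- -1e4
  apply_mask <- function() {
    if (mask_illegal) {
      trans[msk$trans] <<- NEG
      start[msk$start] <<- NEG
    }
  }
  apply_mask()
  m_t <- matrix(0, n, n); v_t <- matrix(0, n, n)
  m_a <- numeric(n); v_a <- numeric(n)
  m_o <- numeric(n); v_o <- numeric(n)
  hist <- numeric(iters)
  for (it in seq_len(iters)) {
    gt <- matrix(0, n, n); ga <- numeric(n); go <- numeric(n)
    nll <- 0
    for (s in seq_along(emissions)) {
      r <- .crf_seq_grad(emissions[[s]], gold[[s]], trans, start, stp)
      gt <- gt + r$g_trans; ga <- ga + r$g_start; go <- go + r$g_stop
      nll <- nll + r$nll
    }
    ns <- length(emissions)
    gt <- gt / ns; ga <- ga / ns; go <- go / ns
    hist[it] <- nll / ns
    up <- function(m, v, g) {
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g * g
      list(m = m, v = v,
           d = lr * (m / (1 - 0.9^it)) / (sqrt(v / (1 - 0.999^it)) + 1e-8))
    }
    u <- up(m_t, v_t, gt); m_t <- u$m; v_t <- u$v; trans <- trans - u$d
    u <- up(m_a, v_a, ga); m_a <- u$m; v_a <- u$v; start <- start - u$d
    u <- up(m_o, v_o, go); m_o <- u$m; v_o <- u$v; stp <- stp - u$d
    apply_mask()
  }
  structure(list(trans = trans, start = start, stop = stp, tags = tags,
                 nll = hist, mask_illegal = mask_illegal),
            class = "crf_params")
}

#' Extract entity spans from a BIO tag sequence
#'
#' Each maximal \code{B-X (I-X)*} run becomes one span.  A stray \code{I-X}
#' without a compatible head is repaired as \code{B-X} (policy
#' \code{"repair"}) or dropped (\code{"drop"}).
#'
#' @param tags character vector of BIO tags.
#' @param stray one of \code{"repair"} (default) or \code{"drop"}.
#' @return data frame with columns \code{code}, \code{start}, \code{end}
#'   (0-based half-open character offsets).
#' @export
extract_entities <- function(tags, stray = c("repair", "drop")) {
  stray <- match.arg(stray)
  out_code <- character(); out_s <- integer(); out_e <- integer()
  cur_code <- NULL; cur_s <- NA_integer_
  close_span <- function(endpos) {
    if (!is.null(cur_code)) {
      out_code[length(out_code) + 1L] <<- cur_code
      out_s[length(out_s) + 1L] <<- cur_s - 1L  # to 0-based
      out_e[length(out_e) + 1L] <<- endpos      # half-open
    }
    cur_code <<- NULL
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      close_span(i - 1L)
    } else if (startsWith(tg, "B-")) {
      close_span(i - 1L)
      cur_code <- substring(tg, 3L); cur_s <- i
    } else { # I-X
      code <- substring(tg, 3L)
      if (!is.null(cur_code) && cur_code == code) {
        # continue
      } else {
        close_span(i - 1L)
        if (stray == "repair") {
          cur_code <- code; cur_s <- i
        }
      }
    }
  }
  close_span(length(tags))
  data.frame(code = out_code, start = out_s, end = out_e,
             stringsAsFactors = FALSE)
}

#' Entity-level precision, recall and F1
#'
#' Exact span-and-type matching: a predicted span counts as a true positive
#' only if a gold span with the same sentence, offsets and type exists.
#' \eqn{P = TP/(TP+FP)}, \eqn{R = TP/(TP+FN)}, \eqn{F1 = 2PR/(P+R)}, with
#' value 0 whenever a denominator is 0.  Reported on the percent scale.
#'
#' @param pred,gold lists of BIO tag vectors (one per sentence), aligned.
#' @param per_type also compute per-type metrics.
#' @return list with \code{overall} (named vector \code{P}, \code{R},
#'   \code{F1}, percentages) and, when requested, \code{per_type} (data
#'   frame).
#' @export
evaluate_ner <- function(pred, gold, per_type = TRUE) {
  if (length(pred) != length(gold)) stop("pred/gold sentence counts differ")
  key <- function(sid, sp) {
    if (!nrow(sp)) return(character())
    paste(sid, sp$start, sp$end, sp$code, sep = ":")
  }
  pk <- character(); gk <- character()
  for (s in seq_along(pred)) {
    if (length(pred[[s]]) != length(gold[[s]])) {
      stop("sentence ", s, ": pred/gold lengths differ")
    }
    pk <- c(pk, key(s, extract_entities(pred[[s]])))
    gk <- c(gk, key(s, extract_entities(gold[[s]])))
  }
  prf <- function(pkeys, gkeys) {
    tp <- length(intersect(pkeys, gkeys))
    p <- if (length(pkeys)) tp / length(pkeys) else 0
    r <- if (length(gkeys)) tp / length(gkeys) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(P = 100 * p, R = 100 * r, F1 = 100 * f)
  }
  out <- list(overall = prf(pk, gk))
  if (per_type) {
    codes <- sort(unique(c(sub("^.*:", "", pk), sub("^.*:", "", gk))))
    pt <- lapply(codes, function(cd) {
      prf(pk[endsWith(pk, paste0(":", cd))],
          gk[endsWith(gk, paste0(":", cd))])
    })
    out$per_type <- data.frame(code = codes, do.call(rbind, pt),
                               stringsAsFactors = FALSE)
  }
  out
}

#' Write evaluation metrics as JSON
#'
#' @param metrics result of [evaluate_ner()].
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  obj <- list(overall = as.list(round(metrics$overall, 2)))
  if (!is.null(metrics$per_type)) {
    pt <- metrics$per_type
    obj$per_type <- stats::setNames(
      lapply(seq_len(nrow(pt)), function(i) {
        list(P = round(pt$P[i], 2), R = round(pt$R[i], 2),
             F1 = round(pt$F1[i], 2))
      }), pt$code)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
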