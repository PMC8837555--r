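# PWM log-odds scanning with exact p-values.
#
# Scores are log2(prob/background) summed over positions ("bits"). The
# null distribution of the score of a random background word is computed
# exactly by dynamic programming over a discretized score lattice, which is
# what makes a hard p-value cutoff (default 1e-3) well defined.

# 4 x K matrix of per-position log-odds, rows A,C,G,T
pwm_logodds <- function(pwm) {
  log2(pwm$probs / pwm$background)
}

# PWM scoring the reverse complement: position k of the '-' matrix is the
# complement row of position K+1-k.
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[4:1, ncol(pwm$probs):1, drop = FALSE]
  rownames(probs) <- ALPHABET
  bg <- pwm$background[4:1]
  structure(list(name = pwm$name, probs = probs, background = bg,
                 length = pwm$length), class = "pwm")
}

#' Log-odds score of a word against a PWM
#'
#' Score in bits: `sum_k log2(probs[k][base_k] / background[base_k])`.
#' On the `'-'` strand the reverse complement of the word is scored.
#'
#' @param pwm a `pwm`.
#' @param word character scalar of length `K = pwm$length` over
#'   `{A,C,G,T}`.
#' @param strand `'+'` or `'-'`.
#' @return score in bits, or `NA` if the word contains any other letter
#'   (such words are skipped by the scanner, never scored).
#' @export
log_odds_score <- function(pwm, word, strand = "+") {
  stopifnot(inherits(pwm, "pwm"), strand %in% c("+", "-"))
  word <- toupper(word)
  if (nchar(word) != pwm$length)
    stopf("word length %d != PWM length %d", nchar(word), pwm$length)
  if (strand == "-") word <- revcomp(word)
  code <- encode_seq(word)
  if (anyNA(code)) return(NA_real_)
  lo <- pwm_logodds(pwm)
  sum(lo[cbind(code, seq_along(code))])
}

# Integer score matrix for the discretized lattice plus the granularity
# actually used (coarsened so that the score range spans <= max_cells).
pwm_int_scores <- function(pwm, granularity = 1e-3, max_cells = 1e5) {
  lo <- pwm_logodds(pwm)
  range_bits <- sum(apply(lo, 2, max) - apply(lo, 2, min))
  g <- max(granularity, range_bits / max_cells)
  list(int = round(lo / g), g = g)
}

#' Exact null distribution of a PWM score
#'
#' Computes, by position-wise dynamic programming (convolution over
#' positions), the exact distribution of the discretized log-odds score of
#' a random word drawn from the background model, and returns the survival
#' function `p(s) = P(S >= s)`.
#'
#' @param pwm a `pwm`.
#' @param granularity score discretization step in bits (default 1e-3; the
#'   step is automatically coarsened so the lattice stays below `1e5`
#'   cells).
#' @return object of class `score_distribution`: list with `granularity`,
#'   `offset` (integer score of the first cell), `pmf` and `cdf` (survival
#'   probabilities, non-increasing in score).
#' @export
score_pvalue_table <- function(pwm, granularity = 1e-3) {
  stopifnot(inherits(pwm, "pwm"), granularity > 0)
  isc <- pwm_int_scores(pwm, granularity)
  int <- isc$int
  K <- ncol(int)
  lo_min <- sum(apply(int, 2, min))
  lo_max <- sum(apply(int, 2, max))
  ncell <- lo_max - lo_min + 1L
  if (ncell <= 1L)
    stopf("granularity too coarse: all scores collapse to one cell")
  pmf <- numeric(ncell)
  pmf[1] <- 1  # before any position: score 0 relative to running offset
  off <- 0L    # integer score of pmf[1]
  bg <- pwm$background
  for (k in seq_len(K)) {
    smin <- min(int[, k]); smax <- max(int[, k])
    cur_n <- length(pmf)
    new_n <- cur_n + (smax - smin)
    new <- numeric(new_n)
    for (b in 1:4) {
      sh <- int[b, k] - smin
      idx <- seq_len(cur_n) + sh
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new
    off <- off + smin
    # trim zero tails to keep the vector tight
    nz <- which(pmf > 0)
    if (length(nz)) {
      off <- off + nz[1] - 1L
      pmf <- pmf[nz[1]:nz[length(nz)]]
    }
  }
  cdf <- rev(cumsum(rev(pmf)))
  structure(list(granularity = isc$g, offset = off, pmf = pmf, cdf = cdf,
                 int_scores = isc$int),
            class = "score_distribution")
}

#' Exact p-value of a score
#'
#' @param dist a `score_distribution` from [score_pvalue_table()].
#' @param int_score integer (discretized) score, i.e. the sum of the
#'   distribution's per-position integer scores for the word.
#' @return `P(S >= int_score)` under the background model, in `(0, 1]`.
#' @export
score_pvalue <- function(dist, int_score) {
  idx <- int_score - dist$offset + 1L
  idx <- pmin(pmax(idx, 1L), length(dist$cdf) + 1L)
  ifelse(idx > length(dist$cdf), 0, dist$cdf[idx])
}

# Vectorized sliding-window scores over an encoded sequence.
# Returns exact float score and integer lattice score per offset; offsets
# whose window contains N give NA.
slide_scores <- function(code, lo, int) {
  K <- ncol(lo)
  L <- length(code)
  n <- L - K + 1L
  if (n < 1L) return(list(score = numeric(0), iscore = integer(0)))
  sc <- numeric(n)
  isc <- numeric(n)
  for (k in seq_len(K)) {
    b <- code[k:(n + k - 1L)]
    sc <- sc + lo[cbind(b, rep.int(k, n))]
    isc <- isc + int[cbind(b, rep.int(k, n))]
  }
  list(score = sc, iscore = isc)
}

#' Scan a sequence for PWM matches on both strands
#'
#' Every offset on both strands is scored; hits whose exact p-value is at
#' most `p_cutoff` are returned, sorted by start then strand (`'+'` before
#' `'-'`). Windows containing `N` are skipped (counted in a message).
#' Overlapping hits are all reported; selection of a single best hit per
#' region happens later in [best_hit_in_interval()].
#'
#' @param pwm a `pwm`.
#' @param seq character scalar, the sequence to scan.
#' @param chrom sequence name recorded in the hits.
#' @param p_cutoff p-value cutoff in `(0, 1]` (default `1e-3`, the
#'   conventional threshold for associating anchors with motifs).
#' @param dist optional precomputed [score_pvalue_table()] for `pwm`
#'   (computed on the fly when absent).
#' @param offset0 0-based coordinate of the first base of `seq` on `chrom`
#'   (default 0); added to hit coordinates.
#' @return data frame of hits: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `score` (bits), `pvalue`.
#' @export
scan_sequence <- function(pwm, seq, chrom = "seq", p_cutoff = 1e-3,
                          dist = NULL, offset0 = 0L) {
  stopifnot(inherits(pwm, "pwm"), p_cutoff > 0, p_cutoff <= 1)
  if (is.null(dist)) dist <- score_pvalue_table(pwm)
  K <- pwm$length
  seq <- toupper(seq)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric())
  if (nchar(seq) < K) return(empty)
  code <- encode_seq(seq)
  lo_f <- pwm_logodds(pwm)
  int_f <- dist$int_scores
  rc <- pwm_revcomp(pwm)
  lo_r <- pwm_logodds(rc)
  # the '-' strand integer lattice must reuse the same per-position cells:
  # position k of the rc matrix is complement of position K+1-k
  int_r <- int_f[4:1, K:1, drop = FALSE]
  hits <- list()
  n_skipped <- 0L
  for (str in c("+", "-")) {
    ss <- if (str == "+") slide_scores(code, lo_f, int_f) else
      slide_scores(code, lo_r, int_r)
    ok <- !is.na(ss$score)
    n_skipped <- n_skipped + sum(!ok)
    pv <- rep(NA_real_, length(ss$score))
    pv[ok] <- score_pvalue(dist, ss$iscore[ok])
    keep <- ok & pv <= p_cutoff
    if (any(keep)) {
      st <- which(keep) - 1L + offset0
      hits[[str]] <- data.frame(chrom = chrom, start = st, end = st + K,
                                strand = str, score = ss$score[keep],
                                pvalue = pv[keep],
                                stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0)
    message(sprintf("scan_sequence: %d window(s) containing N skipped",
                    n_skipped))
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best motif hit fully contained in an interval
#'
#' Among hits fully contained in `interval`, returns the single
#' highest-score hit; ties are broken by lowest start, then `'+'` strand.
#'
#' @param hits hit data frame from [scan_sequence()].
#' @param interval one-row data frame (or list) with `chrom`, `start`,
#'   `end`.
#' @return one-row hit data frame, or `NULL` when no hit is contained.
#' @export
best_hit_in_interval <- function(hits, interval) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  inside <- hits$chrom == interval$chrom &
    hits$start >= interval$start & hits$end <= interval$end
  if (!any(inside)) return(NULL)
  h <- hits[inside, , drop = FALSE]
  ord <- order(-h$score, h$start, h$strand)
  out <- h[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact-match consensus scan
#'
#' Finds exact occurrences of a consensus word on both strands. Scores are
#' the match count (= word length) and p-values are set to 1; this is the
#' light-weight scan used when only the location of a literal word such as
#' GGGAGGG is needed. Overlapping occurrences are all reported.
#'
#' @param seq character scalar to scan.
#' @param consensus word over `{A,C,G,T}`.
#' @param chrom sequence name recorded in the hits.
#' @param offset0 0-based coordinate of the first base of `seq`.
#' @return hit data frame as in [scan_sequence()].
#' @export
consensus_scan <- function(seq, consensus, chrom = "seq", offset0 = 0L) {
  consensus <- toupper(consensus)
  stopifnot(!grepl("[^ACGT]", consensus))
  seq <- toupper(seq)
  K <- nchar(consensus)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric())
  if (nchar(seq) < K) return(empty)
  find_all <- function(pattern) {
    # overlapping exact matches via lookahead-free stepping
    res <- integer(0)
    from <- 1L
    repeat {
      m <- regexpr(pattern, substr(seq, from, nchar(seq)), fixed = TRUE)
      if (m == -1L) break
      pos <- from + as.integer(m) - 1L
      res <- c(res, pos)
      from <- pos + 1L
    }
    res
  }
  rc <- revcomp(consensus)
  rows <- list()
  fwd <- find_all(consensus)
  if (length(fwd)) {
    rows$f <- data.frame(chrom = chrom, start = fwd - 1L + offset0,
                         end = fwd - 1L + K + offset0, strand = "+",
                         score = K, pvalue = 1, stringsAsFactors = FALSE)
  }
  rev_ <- if (rc == consensus) integer(0) else find_all(rc)
  if (length(rev_)) {
    rows$r <- data.frame(chrom = chrom, start = rev_ - 1L + offset0,
                         end = rev_ - 1L + K + offset0, strand = "-",
                         score = K, pvalue = 1, stringsAsFactors = FALSE)
  }
  if (rc == consensus && length(fwd)) {
    # palindromic word: report both strands at each site
    rows$p <- transform(rows$f, strand = "-")
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6
#'
#' Score column is bits x 100, rounded; strand column populated.
#'
#' @param hits hit data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed6 <- function(hits, path) {
  lines <- if (nrow(hits)) {
    paste(hits$chrom, hits$start, hits$end,
          sprintf("hit_%d", seq_len(nrow(hits))),
          round(hits$score * 100), hits$strand, sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
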