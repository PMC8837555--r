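# Shared fixtures and independent oracles. The oracles deliberately use
# the dumbest possible algorithms (full enumeration, per-position loops,
# alternating normalization) so they stay independent of the package's
# vectorized/dynamic-programming implementations.

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# naive O(L * K) rescoring oracle for scan_sequence: loops over every
# offset and strand, scores base by base, p-value from the same exact
# null table (the scanning path under test never touches this code)
naive_scan <- function(pwm, seq, p_cutoff = 1e-3, dist = NULL) {
  if (is.null(dist)) dist <- score_pvalue_table(pwm)
  K <- pwm$length
  L <- nchar(seq)
  lo <- log2(pwm$probs / pwm$background)
  int <- dist$int_scores
  bases_fwd <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  rows <- list()
  if (L >= K) {
    ks <- seq_len(K)
    for (start in 0:(L - K)) {
      word_fwd <- bases_fwd[(start + 1):(start + K)]
      for (strand in c("+", "-")) {
        b <- if (strand == "-") rev(comp[word_fwd]) else word_fwd
        if (anyNA(b)) next
        sc <- sum(lo[cbind(b, ks)])
        isc <- sum(int[cbind(b, ks)])
        pv <- score_pvalue(dist, isc)
        if (pv <= p_cutoff) {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = "seq", start = start, end = start + K,
            strand = strand, score = sc, pvalue = pv,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pvalue = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive 4^K enumeration of the discretized score null
enumerate_pvalue <- function(pwm, dist, int_score) {
  K <- pwm$length
  int <- dist$int_scores
  bg <- pwm$background
  words <- expand.grid(rep(list(1:4), K))
  total <- 0
  for (r in seq_len(nrow(words))) {
    b <- as.integer(words[r, ])
    isc <- sum(int[cbind(b, seq_len(K))])
    if (isc >= int_score) total <- total + prod(bg[b])
  }
  total
}

# alternating row/column normalization (Sinkhorn) oracle for ICE;
# returns the matrix scaled to unit row sums
sinkhorn_oracle <- function(M, iters = 2000) {
  W <- M
  for (i in seq_len(iters)) {
    rs <- rowSums(W)
    W <- W / rs
    cs <- colSums(W)
    W <- sweep(W, 2, cs, "/")
  }
  W / rowSums(W)
}

# deterministic small contact matrix with planted decay
decay_matrix <- function(n, depth = 1e5, alpha = 1, chrom = "chrT",
                         bin_size = 20000) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- (d + 1)^(-alpha)
  E <- E * depth / sum(E[upper.tri(E, diag = TRUE)])
  contact_matrix(chrom, bin_size, E)
}
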