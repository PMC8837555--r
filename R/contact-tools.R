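# Binned contact-matrix computations: ICE balancing, distance-decay
# expected profiles, aggregate peak analysis (APA) with P2LL, insulation
# style boundary scores / TAD calls, intra-TAD activity, differential
# loop/TAD activity, and a simple Poisson loop caller for synthetic
# end-to-end runs.

#' Bin read pairs into a contact matrix
#'
#' Pairs closer than `min_pair_distance` are dropped (short-range ligation
#' noise), the remainder tallied into `bin_size` bins and symmetrized.
#'
#' @param pairs data frame with columns `chrom`, `pos1`, `pos2` (0-based
#'   bp).
#' @param chrom chromosome to bin (others ignored).
#' @param chrom_size chromosome length in bp (sets the bin count).
#' @param bin_size bin size in bp (default 20000, i.e. 20-kb bins).
#' @param min_pair_distance minimum |pos2 - pos1| in bp (default 25000).
#' @return a [contact_matrix()].
#' @export
bin_contacts <- function(pairs, chrom, chrom_size, bin_size = 20000,
                         min_pair_distance = 25000) {
  sel <- pairs$chrom == chrom
  p1 <- pairs$pos1[sel]
  p2 <- pairs$pos2[sel]
  if (any(p1 < 0 | p2 < 0)) stopf("negative position in pairs")
  if (any(p1 >= chrom_size | p2 >= chrom_size))
    stopf("position beyond chromosome end")
  keep <- abs(p2 - p1) >= min_pair_distance
  p1 <- p1[keep]; p2 <- p2[keep]
  n_bins <- as.integer(ceiling(chrom_size / bin_size))
  counts <- matrix(0, n_bins, n_bins)
  if (length(p1)) {
    b1 <- p1 %/% bin_size + 1L
    b2 <- p2 %/% bin_size + 1L
    for (k in seq_along(b1)) {
      counts[b1[k], b2[k]] <- counts[b1[k], b2[k]] + 1
      if (b1[k] != b2[k]) counts[b2[k], b1[k]] <- counts[b2[k], b1[k]] + 1
    }
  }
  contact_matrix(chrom, bin_size, counts)
}

#' Iterative correction (ICE) balancing
#'
#' Equalizes bin visibility by iteratively dividing the matrix by the
#' product of its row and column coverage until all unmasked row sums
#' agree. All-zero bins plus the lowest-coverage `mask_fraction` of
#' nonzero bins are masked first. The balanced layer is rescaled so its
#' total equals the unmasked raw total; per-bin multiplicative biases are
#' returned (`counts[i,j] = biases[i] * biases[j] * balanced[i,j]` up to
#' the global rescale).
#'
#' @param cm a [contact_matrix()].
#' @param tol convergence tolerance on the maximum relative deviation of
#'   unmasked row sums (default 1e-6).
#' @param max_iter maximum iterations (default 500).
#' @param mask_fraction fraction of lowest-coverage nonzero bins to mask
#'   (default 0.02).
#' @return the matrix with `balanced`, `biases` and `mask` filled in.
#' @export
ice_balance <- function(cm, tol = 1e-6, max_iter = 500,
                        mask_fraction = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$n_bins
  cov <- rowSums(cm$counts)
  mask <- cov == 0
  nz <- which(!mask)
  n_low <- floor(mask_fraction * length(nz))
  if (n_low > 0) mask[nz[order(cov[nz])[seq_len(n_low)]]] <- TRUE
  if (all(mask)) stopf("all bins masked; nothing to balance")
  W <- cm$counts
  W[mask, ] <- 0
  W[, mask] <- 0
  biases <- rep(1, n)
  converged <- FALSE
  dev <- NA_real_
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    sm <- s[!mask]
    dev <- max(abs(sm / mean(sm) - 1))
    if (dev < tol) { converged <- TRUE; break }
    db <- s / mean(sm)
    db[mask | db == 0] <- 1
    W <- W / outer(db, db)
    biases <- biases * db
  }
  if (!converged)
    stopf("ICE did not converge in %d iterations (last deviation %.3g)",
          max_iter, dev)
  # rescale so the balanced total matches the unmasked raw total
  raw_total <- sum(cm$counts[!mask, !mask])
  bal_total <- sum(W)
  if (bal_total > 0) W <- W * (raw_total / bal_total)
  W[mask, ] <- NA
  W[, mask] <- NA
  biases[mask] <- NA
  contact_matrix(cm$chrom, cm$bin_size, cm$counts,
                 balanced = W, biases = biases, mask = mask)
}

# matrix layer to analyze: balanced when present, else raw (with a note)
working_layer <- function(cm, quiet = FALSE) {
  if (!is.null(cm$balanced)) return(cm$balanced)
  if (!quiet) message("using raw counts (no balanced layer present)")
  M <- cm$counts
  if (any(cm$mask)) { M[cm$mask, ] <- NA; M[, cm$mask] <- NA }
  M
}

#' Mean contact by bin distance
#'
#' For each bin distance `d` the mean over unmasked pixels at that
#' distance, computed on the balanced layer when present (raw otherwise).
#'
#' @param cm a [contact_matrix()].
#' @param smooth logical; if `TRUE` the profile is made non-increasing in
#'   distance by a running minimum of means (isotonic-style clean-up for
#'   sparse far diagonals). Default `FALSE`.
#' @return numeric vector of length `n_bins`, element `d + 1` holding the
#'   mean at distance `d` (the first element is the diagonal mean).
#' @export
expected_by_distance <- function(cm, smooth = FALSE) {
  M <- working_layer(cm)
  n <- nrow(M)
  prof <- vapply(0:(n - 1L), function(d) {
    v <- M[cbind(1:(n - d), (1 + d):n)]
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }, numeric(1))
  if (smooth) prof <- cummin(ifelse(is.na(prof), Inf, prof))
  prof
}

# observed / expected matrix from the working layer
oe_matrix <- function(cm, expected = NULL) {
  M <- working_layer(cm)
  n <- nrow(M)
  if (is.null(expected)) expected <- expected_by_distance(cm)
  D <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
  E <- matrix(expected[D], n, n)
  OE <- M / E
  OE[E == 0] <- NA
  OE
}

#' Aggregate peak analysis
#'
#' For every usable loop, the `(2N+1) x (2N+1)` window of the
#' observed/expected matrix centered on the loop pixel (the pair of anchor
#' midpoint bins) is extracted and averaged across loops. Loops whose
#' window would cross the diagonal (anchor bin distance `< 2N + 2`) or the
#' matrix edge are skipped and counted. Set `normalize = "raw"` to
#' aggregate the working layer without O/E normalization.
#'
#' @param cm a [contact_matrix()] whose `bin_size` equals `resolution`.
#' @param loops loop data frame on the matrix chromosome.
#' @param resolution expected bin size in bp (default 5000; APA is
#'   conventionally shown at 5-kb resolution). A mismatch with the matrix
#'   is an error — no silent re-binning.
#' @param flank_bins N, the number of flanking bins on each side
#'   (default 10).
#' @param normalize `"oe"` (default) or `"raw"`.
#' @return object of class `apa_result`: list with `aggregate` matrix
#'   (rows = upstream-anchor offsets), `n_loops_used`, `n_loops_skipped`,
#'   `p2ll`, `resolution`.
#' @export
apa <- function(cm, loops, resolution = 5000, flank_bins = 10,
                normalize = c("oe", "raw")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$bin_size != resolution)
    stopf("matrix bin size (%d) != APA resolution (%d); re-bin the input",
          cm$bin_size, resolution)
  N <- as.integer(flank_bins)
  M <- if (normalize == "oe") oe_matrix(cm) else working_layer(cm)
  n <- nrow(M)
  agg <- matrix(0, 2 * N + 1, 2 * N + 1)
  used <- 0L
  skipped <- 0L
  loops <- loops[loops$chrom == cm$chrom, , drop = FALSE]
  for (i in seq_len(nrow(loops))) {
    bi <- floor(interval_mid(loops$start5[i], loops$end5[i]) /
                  cm$bin_size) + 1L
    bj <- floor(interval_mid(loops$start3[i], loops$end3[i]) /
                  cm$bin_size) + 1L
    if (bj - bi < 2 * N + 2 ||
        bi - N < 1 || bi + N > n || bj - N < 1 || bj + N > n) {
      skipped <- skipped + 1L
      next
    }
    sub <- M[(bi - N):(bi + N), (bj - N):(bj + N)]
    if (anyNA(sub)) { skipped <- skipped + 1L; next }
    agg <- agg + sub
    used <- used + 1L
  }
  if (used == 0L) stopf("no loops after filtering")
  agg <- agg / used
  structure(list(aggregate = agg, n_loops_used = used,
                 n_loops_skipped = skipped,
                 p2ll = p2ll(agg), resolution = resolution),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA: %d loops used (%d skipped), %d bp bins, P2LL = %.3f\n",
              x$n_loops_used, x$n_loops_skipped, x$resolution, x$p2ll))
  invisible(x)
}

#' Peak-to-lower-left ratio of an APA aggregate
#'
#' The central pixel divided by the mean of the `corner_bins` x
#' `corner_bins` block in the lower-left corner. With rows indexed by the
#' upstream-anchor offset, the corner nearest the diagonal is the block
#' with the lowest row and column indices (configurable via `corner`).
#'
#' @param aggregate odd-sized square matrix.
#' @param corner_bins corner block size; default `floor(width / 3)`.
#' @param corner which corner to use: `"ll"` (default; lowest row/col
#'   indices), `"ul"`, `"lr"` or `"ur"`.
#' @return positive real; 1 means no central enrichment.
#' @export
p2ll <- function(aggregate, corner_bins = NULL,
                 corner = c("ll", "ul", "lr", "ur")) {
  corner <- match.arg(corner)
  w <- nrow(aggregate)
  stopifnot(w == ncol(aggregate), w %% 2 == 1)
  if (is.null(corner_bins)) corner_bins <- max(1L, w %/% 3L)
  stopifnot(corner_bins < (w + 1) %/% 2)
  c0 <- (w + 1) %/% 2
  lo <- seq_len(corner_bins)
  hi <- (w - corner_bins + 1):w
  blk <- switch(corner,
                ll = aggregate[lo, lo],
                ul = aggregate[hi, lo],
                lr = aggregate[lo, hi],
                ur = aggregate[hi, hi])
  cmean <- mean(blk)
  if (!is.finite(cmean) || cmean == 0) stopf("corner mean is zero")
  aggregate[c0, c0] / cmean
}

#' Loop distance histogram
#'
#' Histogram of anchor-midpoint distances plus the fraction of loops
#' closer than 2 Mb (most chromatin loops fall below that span).
#'
#' @param loops loop data frame with a `distance` column.
#' @param bin_edges histogram breaks in bp (default 100-kb bins to 5 Mb,
#'   with one overflow bin).
#' @param threshold_bp distance threshold for the reported fraction
#'   (default 2e6).
#' @return list with `histogram` (data frame `bin_lo`, `bin_hi`, `count`)
#'   and `fraction_below` (NA and a warning when there are no loops).
#' @export
loop_distance_histogram <- function(loops,
                                    bin_edges = c(seq(0, 5e6, by = 1e5),
                                                  Inf),
                                    threshold_bp = 2e6) {
  d <- loops$distance
  if (length(d) == 0) {
    warnf("no loops: distance fraction undefined")
    return(list(histogram = data.frame(bin_lo = numeric(),
                                       bin_hi = numeric(),
                                       count = integer()),
                fraction_below = NA_real_))
  }
  cuts <- hist(pmin(d, max(bin_edges[is.finite(bin_edges)])),
               breaks = bin_edges[is.finite(bin_edges)],
               plot = FALSE, right = FALSE)
  counts <- cuts$counts
  edges <- bin_edges[is.finite(bin_edges)]
  histogram <- data.frame(bin_lo = edges[-length(edges)],
                          bin_hi = edges[-1], count = counts)
  list(histogram = histogram,
       fraction_below = mean(d < threshold_bp))
}

#' Insulation-style boundary score
#'
#' For bin `i` with `W = window_bp / bin_size`, the score is the mean of
#' the cross pixels `{(a, b): i - W <= a < i < b <= i + W}` divided by the
#' mean of the two flanking intra-window triangles. Boundaries insulate,
#' so they have noticeably LOWER scores than their neighborhood (the
#' "ratio" orientation is cross / intra). Bins without a full flanking
#' window, and masked bins, give `NA`.
#'
#' @param cm a [contact_matrix()] (balanced layer used when present).
#' @param window_bp window size in bp; conventionally 250 kb, 500 kb or
#'   1 Mb at 20-kb bins (default 500000, the insulating window used for
#'   TAD calls).
#' @return object of class `boundary_track`: list with `chrom`,
#'   `bin_size`, `window_bp`, `scores` (per-bin, NA where undefined).
#' @export
boundary_score <- function(cm, window_bp = 500000) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (window_bp %% cm$bin_size != 0)
    stopf("window_bp must be a multiple of bin_size")
  W <- as.integer(window_bp / cm$bin_size)
  n <- cm$n_bins
  if (2L * W + 1L > n) stopf("window larger than chromosome")
  M <- working_layer(cm, quiet = TRUE)
  scores <- rep(NA_real_, n)
  for (i in (W + 1L):(n - W)) {
    cross <- M[(i - W):(i - 1L), (i + 1L):(i + W)]
    left <- M[(i - W):(i - 1L), (i - W):(i - 1L)]
    right <- M[(i + 1L):(i + W), (i + 1L):(i + W)]
    intra <- c(left[upper.tri(left)], right[upper.tri(right)])
    num <- mean(cross, na.rm = TRUE)
    den <- mean(intra, na.rm = TRUE)
    if (is.finite(num) && is.finite(den) && den > 0)
      scores[i] <- num / den
  }
  structure(list(chrom = cm$chrom, bin_size = cm$bin_size,
                 window_bp = as.integer(window_bp), scores = scores),
            class = "boundary_track")
}

#' Call TAD boundaries from a boundary-score track
#'
#' Boundaries are local minima of the score whose z-value (against the
#' mean and SD of the defined part of the track) is at most `-z_cutoff`.
#' A flat track (SD ~ 0) yields no boundaries.
#'
#' @param track a `boundary_track` from [boundary_score()].
#' @param z_cutoff positive z threshold (default 1).
#' @return integer vector of 0-based boundary bin indices.
#' @export
call_boundaries <- function(track, z_cutoff = 1) {
  s <- track$scores
  n <- length(s)
  mu <- mean(s, na.rm = TRUE)
  sd_ <- stats::sd(s, na.rm = TRUE)
  if (!is.finite(sd_) || sd_ < 1e-12 * max(1, abs(mu))) return(integer(0))
  z <- (s - mu) / sd_
  # collapse exact-tie plateaus to runs; a run is a local minimum when the
  # defined neighbors on both sides are strictly greater
  def <- which(!is.na(s))
  if (!length(def)) return(integer(0))
  r <- rle(s[def])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in seq_along(r$values)) {
    lft <- if (k > 1) r$values[k - 1] else Inf
    rgt <- if (k < length(r$values)) r$values[k + 1] else Inf
    if (r$values[k] < lft && r$values[k] < rgt) {
      i <- def[starts[k]]  # first bin of the run
      if (z[i] <= -z_cutoff) out <- c(out, i - 1L)
    }
  }
  out
}

#' TAD intervals between consecutive boundaries
#'
#' @param boundaries 0-based boundary bin indices (from
#'   [call_boundaries()]).
#' @param n_bins number of bins on the chromosome.
#' @param bin_size bin size in bp.
#' @param chrom chromosome name.
#' @return data frame of TADs with `chrom`, `start`, `end` (bp), `bin_lo`,
#'   `bin_hi` (0-based, half-open in bins); boundaries become TAD edges
#'   and the chromosome ends close the first and last TAD.
#' @export
tads_from_boundaries <- function(boundaries, n_bins, bin_size,
                                 chrom = "chr") {
  b <- sort(unique(as.integer(boundaries)))
  edges <- c(0L, b[b > 0 & b < n_bins], n_bins)
  edges <- unique(edges)
  data.frame(chrom = chrom,
             start = edges[-length(edges)] * bin_size,
             end = edges[-1] * bin_size,
             bin_lo = edges[-length(edges)],
             bin_hi = edges[-1],
             stringsAsFactors = FALSE)
}

#' Intra-TAD activity
#'
#' Per-TAD mean of the observed/expected balanced matrix over all
#' (unmasked) intra-TAD pixels — a relative magnitude: 1 means contacts at
#' the chromosome-wide distance expectation, above 1 enriched.
#'
#' @param cm a [contact_matrix()] (balanced layer recommended).
#' @param tads TAD data frame from [tads_from_boundaries()].
#' @param expected optional precomputed [expected_by_distance()] profile.
#' @return `tads` with an `activity` column (and `flag_small` for TADs
#'   under 3 bins, whose means are unstable).
#' @export
intra_tad_activity <- function(cm, tads, expected = NULL) {
  OE <- oe_matrix(cm, expected)
  act <- numeric(nrow(tads))
  for (t in seq_len(nrow(tads))) {
    lo <- tads$bin_lo[t] + 1L
    hi <- tads$bin_hi[t]
    sub <- OE[lo:hi, lo:hi]
    vals <- sub[upper.tri(sub, diag = TRUE)]
    act[t] <- mean(vals, na.rm = TRUE)
  }
  tads$activity <- act
  tads$flag_small <- (tads$bin_hi - tads$bin_lo) < 3L
  tads
}

#' Differential loop/TAD activity between two conditions
#'
#' Counts are CPM-normalized per sample; the per-feature log2 fold change
#' is computed between mean CPMs (with a +0.5 CPM prior), and the p-value
#' comes from a two-sided exact Poisson rate test on pooled counts
#' (conditional binomial test with the library-size split as the null
#' proportion), BH-corrected across features. A feature is significant
#' when `fdr <= fdr_cutoff` and `|log2fc| >= lfc_cutoff`.
#'
#' @param counts_a,counts_b integer matrices, features x replicates, for
#'   conditions A (reference, e.g. WT) and B (e.g. KO).
#' @param fdr_cutoff BH FDR threshold (default 0.005, the conventional
#'   loop-activity cutoff; use 0.05 with `lfc_cutoff = 0` for TADs).
#' @param lfc_cutoff |log2 fold change| threshold (default 1.5).
#' @param lib_sizes_a,lib_sizes_b optional per-replicate library sizes;
#'   default column sums of the count matrices.
#' @return data frame with one row per feature: `feature`, mean CPMs,
#'   `log2fc` (B vs A), `pvalue`, `fdr`, `significant`.
#' @export
differential_activity <- function(counts_a, counts_b, fdr_cutoff = 0.005,
                                  lfc_cutoff = 1.5, lib_sizes_a = NULL,
                                  lib_sizes_b = NULL) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  stopifnot(nrow(counts_a) == nrow(counts_b),
            all(counts_a >= 0), all(counts_b >= 0))
  if (is.null(lib_sizes_a)) lib_sizes_a <- colSums(counts_a)
  if (is.null(lib_sizes_b)) lib_sizes_b <- colSums(counts_b)
  if (any(lib_sizes_a <= 0) || any(lib_sizes_b <= 0))
    stopf("zero total counts in a condition")
  cpm_a <- sweep(counts_a, 2, lib_sizes_a, "/") * 1e6
  cpm_b <- sweep(counts_b, 2, lib_sizes_b, "/") * 1e6
  mean_a <- rowMeans(cpm_a)
  mean_b <- rowMeans(cpm_b)
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  pooled_a <- rowSums(counts_a)
  pooled_b <- rowSums(counts_b)
  Na <- sum(lib_sizes_a)
  Nb <- sum(lib_sizes_b)
  p0 <- Nb / (Na + Nb)
  pvalue <- vapply(seq_along(pooled_a), function(i) {
    tot <- pooled_a[i] + pooled_b[i]
    if (tot == 0) return(1)
    stats::binom.test(pooled_b[i], tot, p0)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(pvalue, method = "BH")
  data.frame(feature = seq_len(nrow(counts_a)),
             cpm_a = mean_a, cpm_b = mean_b, log2fc = log2fc,
             pvalue = pvalue, fdr = fdr,
             significant = fdr <= fdr_cutoff & abs(log2fc) >= lfc_cutoff)
}

#' Extract per-loop contact counts from a matrix
#'
#' Sums the raw counts in the `(2 * halo + 1)^2` pixel window centered on
#' each loop's anchor-midpoint pixel — the count that feeds
#' [differential_activity()].
#'
#' @param cm a [contact_matrix()].
#' @param loops loop data frame on the matrix chromosome.
#' @param halo window half-width in bins (default 1, i.e. a 3x3 window).
#' @return integer vector of per-loop counts (NA for loops whose window
#'   leaves the matrix).
#' @export
loop_pixel_counts <- function(cm, loops, halo = 1L) {
  n <- cm$n_bins
  vapply(seq_len(nrow(loops)), function(i) {
    bi <- floor(interval_mid(loops$start5[i], loops$end5[i]) /
                  cm$bin_size) + 1L
    bj <- floor(interval_mid(loops$start3[i], loops$end3[i]) /
                  cm$bin_size) + 1L
    if (bi - halo < 1 || bj + halo > n || bi + halo > n || bj - halo < 1)
      return(NA_real_)
    sum(cm$counts[(bi - halo):(bi + halo), (bj - halo):(bj + halo)])
  }, numeric(1))
}

#' Total read-pair count of a contact matrix
#'
#' Sum of the upper triangle including the diagonal — the library size
#' used for CPM normalization of loop/TAD counts.
#'
#' @param cm a [contact_matrix()].
#' @return numeric scalar.
#' @export
matrix_total_pairs <- function(cm) {
  sum(cm$counts[upper.tri(cm$counts, diag = TRUE)])
}

#' Simple Poisson loop caller (synthetic pipelines only)
#'
#' A deliberately simple enrichment caller used to close the loop on
#' synthetic scenarios: each pixel beyond the minimum-distance filter gets
#' a one-sided Poisson p-value of its raw count against the distance
#' expectation scaled to raw units, BH correction is applied, and
#' significant pixels are merged into 8-connected clusters whose maximum
#' pixel is reported as the loop. It makes no claim to the refinements of
#' production loop callers.
#'
#' @param cm a [contact_matrix()].
#' @param fdr_cutoff BH threshold (default 0.05).
#' @param min_dist_bins minimum pixel distance from the diagonal
#'   (default 2).
#' @return loop data frame (`chrom`, `start5`, `end5`, `start3`, `end3`,
#'   `name`, `distance`) of cluster-maximum pixels.
#' @export
simple_loop_call <- function(cm, fdr_cutoff = 0.05, min_dist_bins = 2L) {
  n <- cm$n_bins
  raw <- cm$counts
  if (sum(raw) == 0) stopf("empty matrix: no contacts to call loops from")
  # expected raw count by distance (raw layer, so the Poisson model holds)
  raw_cm <- contact_matrix(cm$chrom, cm$bin_size, raw)
  expected <- expected_by_distance(raw_cm)
  idx <- which(upper.tri(raw), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  keep <- d >= min_dist_bins
  idx <- idx[keep, , drop = FALSE]
  d <- d[keep]
  lambda <- expected[d + 1L]
  x <- raw[idx]
  pv <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
  fdr <- stats::p.adjust(pv, method = "BH")
  sig <- which(fdr <= fdr_cutoff & x > 0)
  empty <- data.frame(chrom = character(), start5 = integer(),
                      end5 = integer(), start3 = integer(),
                      end3 = integer(), name = character(),
                      distance = numeric())
  if (!length(sig)) return(empty)
  pts <- idx[sig, , drop = FALSE]
  vals <- x[sig]
  # 8-connected clustering by union-find over significant pixels
  key <- pts[, 1] * (n + 1L) + pts[, 2]
  parent <- seq_along(sig)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  lookup <- new.env(hash = TRUE)
  for (k in seq_along(sig)) assign(as.character(key[k]), k, envir = lookup)
  for (k in seq_along(sig)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nk <- (pts[k, 1] + di) * (n + 1L) + (pts[k, 2] + dj)
      m <- mget(as.character(nk), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(m)) {
        ra <- find(k); rb <- find(m)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  root <- vapply(seq_along(sig), find, integer(1))
  out <- lapply(unique(root), function(r) {
    members <- which(root == r)
    best <- members[which.max(vals[members])]
    bi <- pts[best, 1]; bj <- pts[best, 2]
    data.frame(chrom = cm$chrom,
               start5 = (bi - 1L) * cm$bin_size,
               end5 = bi * cm$bin_size,
               start3 = (bj - 1L) * cm$bin_size,
               end3 = bj * cm$bin_size,
               name = sprintf("loop_%d_%d", bi - 1L, bj - 1L),
               distance = (bj - bi) * cm$bin_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start5, out$start3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
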