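# Anchor annotation and orientation classification.
#
# A loop is annotated per transcription factor with the best motif hit at
# each anchor, where the search is restricted to the intersection of the
# anchor with that factor's ChIP-seq peaks (this keeps false positives
# down: sequence similarity alone is a weak signal, occupancy + sequence is
# much stronger). The pair of hit strands then classifies the loop as
# convergent (+/-), divergent (-/+) or tandem (same strand); loops with a
# hit at only one anchor stay unclassified.

#' Intersections of a loop's anchors with a peak set
#'
#' @param loop one-row loop data frame (columns `chrom`, `start5`, `end5`,
#'   `start3`, `end3`).
#' @param peaks interval data frame (sorted), as from [read_bed()].
#' @return list with elements `anchor5` and `anchor3`, each a data frame of
#'   `(anchor intersect peak)` sub-intervals (possibly empty). When an
#'   anchor overlaps several peaks, all intersections are returned (the
#'   union of intersections is searched downstream).
#' @export
anchor_search_regions <- function(loop, peaks) {
  one <- function(astart, aend) {
    if (is.null(peaks) || nrow(peaks) == 0) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer()))
    }
    sel <- peaks$chrom == loop$chrom & peaks$start < aend &
      peaks$end > astart
    p <- peaks[sel, , drop = FALSE]
    out <- data.frame(chrom = rep(loop$chrom, nrow(p)),
                      start = pmax(p$start, astart),
                      end = pmin(p$end, aend))
    out[order(out$start), , drop = FALSE]
  }
  list(anchor5 = one(loop$start5, loop$end5),
       anchor3 = one(loop$start3, loop$end3))
}

# max signal of peaks overlapping [astart, aend) on chrom; 0 if none
anchor_peak_signal <- function(chrom, astart, aend, peaks) {
  sel <- peaks$chrom == chrom & peaks$start < aend & peaks$end > astart
  if (!any(sel)) return(0)
  s <- peaks$signal[sel]
  if (all(is.na(s))) return(0)
  max(s, na.rm = TRUE)
}

#' Filter loops by ChIP-seq signal at both anchors
#'
#' A loop is retained only if, for every requested factor, the signal at
#' BOTH anchors is at least that factor's cutoff (a binary threshold). The
#' anchor signal is the maximum signal of overlapping peaks, 0 when no peak
#' overlaps.
#'
#' @param loops loop data frame.
#' @param peaks_by_factor named list of peak data frames (with `signal`).
#' @param cutoffs named numeric vector of per-factor cutoffs (>= 0); names
#'   must be a subset of `names(peaks_by_factor)`.
#' @return the retained loops; per-factor retained counts are reported via
#'   `message()`.
#' @export
filter_loops_by_signal <- function(loops, peaks_by_factor, cutoffs) {
  stopifnot(all(cutoffs >= 0))
  missing_tracks <- setdiff(names(cutoffs), names(peaks_by_factor))
  if (length(missing_tracks))
    stopf("no peak track for factor(s): %s",
          paste(missing_tracks, collapse = ", "))
  keep <- rep(TRUE, nrow(loops))
  for (fac in names(cutoffs)) {
    pk <- peaks_by_factor[[fac]]
    s5 <- vapply(seq_len(nrow(loops)), function(i)
      anchor_peak_signal(loops$chrom[i], loops$start5[i], loops$end5[i], pk),
      numeric(1))
    s3 <- vapply(seq_len(nrow(loops)), function(i)
      anchor_peak_signal(loops$chrom[i], loops$start3[i], loops$end3[i], pk),
      numeric(1))
    pass <- s5 >= cutoffs[[fac]] & s3 >= cutoffs[[fac]]
    keep <- keep & pass
    message(sprintf("filter_loops_by_signal: %s cutoff %g keeps %d/%d loops",
                    fac, cutoffs[[fac]], sum(pass), nrow(loops)))
  }
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the best motif hit per anchor and factor
#'
#' For each loop, anchor and factor, takes the best-scoring motif hit fully
#' contained in the intersection of the anchor with that factor's peaks
#' ([best_hit_in_interval()] over [anchor_search_regions()]). Hits falling
#' inside the anchor but outside every peak are NOT assigned; anchors
#' without peaks get no hit.
#'
#' @param loops loop data frame.
#' @param hits_by_factor named list of hit data frames.
#' @param peaks_by_factor named list of peak data frames.
#' @param p_cutoff hits with `pvalue > p_cutoff` are dropped before
#'   assignment (default 1e-3); a no-op when the scan already applied it.
#' @return data frame with one row per loop x factor: `loop`, `factor`,
#'   strand/score/start of the best hit at each anchor (NA when absent).
#' @export
assign_anchor_motifs <- function(loops, hits_by_factor, peaks_by_factor,
                                 p_cutoff = 1e-3) {
  factors <- names(hits_by_factor)
  res <- list()
  for (fac in factors) {
    hits <- hits_by_factor[[fac]]
    if (!is.null(hits) && nrow(hits))
      hits <- hits[hits$pvalue <= p_cutoff, , drop = FALSE]
    peaks <- peaks_by_factor[[fac]]
    n <- nrow(loops)
    s5 <- s3 <- rep(NA_character_, n)
    sc5 <- sc3 <- st5 <- st3 <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      regs <- anchor_search_regions(loops[i, , drop = FALSE], peaks)
      pick <- function(regions) {
        best <- NULL
        for (r in seq_len(nrow(regions))) {
          h <- best_hit_in_interval(hits, regions[r, , drop = FALSE])
          if (!is.null(h) &&
              (is.null(best) || h$score > best$score ||
               (h$score == best$score &&
                (h$start < best$start ||
                 (h$start == best$start && h$strand < best$strand))))) {
            best <- h
          }
        }
        best
      }
      b5 <- pick(regs$anchor5)
      b3 <- pick(regs$anchor3)
      if (!is.null(b5)) { s5[i] <- b5$strand; sc5[i] <- b5$score
                          st5[i] <- b5$start }
      if (!is.null(b3)) { s3[i] <- b3$strand; sc3[i] <- b3$score
                          st3[i] <- b3$start }
    }
    res[[fac]] <- data.frame(loop = seq_len(n), factor = fac,
                             strand5 = s5, score5 = sc5, start5_hit = st5,
                             strand3 = s3, score3 = sc3, start3_hit = st3,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify loop orientation from anchor motif strands
#'
#' With `s5`, `s3` the strands of the stored hits at the 5' and 3' anchors:
#' `(+,-)` is convergent, `(-,+)` divergent, `(+,+)` or `(-,-)` tandem; if
#' either hit is missing the loop is unclassified (only loops with motifs
#' in both anchors are considered).
#'
#' @param strand5,strand3 strand characters (`'+'`, `'-'` or `NA`),
#'   vectorized.
#' @return character vector over
#'   `{convergent, divergent, tandem, unclassified}`.
#' @export
classify_orientation <- function(strand5, strand3) {
  out <- rep("unclassified", length(strand5))
  both <- !is.na(strand5) & !is.na(strand3)
  out[both & strand5 == "+" & strand3 == "-"] <- "convergent"
  out[both & strand5 == "-" & strand3 == "+"] <- "divergent"
  out[both & strand5 == strand3] <- "tandem"
  out
}

#' Orientation proportions per group
#'
#' Proportions of convergent / tandem / divergent calls over the classified
#' loops of each group (unclassified calls are excluded from the
#' denominator, i.e. proportions are over the sum of the three loop
#' groups). Groups with zero classified loops are flagged with `NA`
#' proportions.
#'
#' @param calls character vector of orientation calls.
#' @param groups group labels, recycled to `length(calls)` (default one
#'   group `"all"`).
#' @return data frame with one row per group: counts `n_convergent`,
#'   `n_tandem`, `n_divergent`, `n_unclassified` and the corresponding
#'   proportions `p_*` (summing to 1 over classified loops).
#' @export
orientation_proportions <- function(calls, groups = "all") {
  groups <- rep_len(as.character(groups), length(calls))
  out <- lapply(sort(unique(groups)), function(g) {
    cl <- calls[groups == g]
    n_conv <- sum(cl == "convergent")
    n_tand <- sum(cl == "tandem")
    n_div <- sum(cl == "divergent")
    n_un <- sum(cl == "unclassified")
    n_cls <- n_conv + n_tand + n_div
    if (n_cls == 0) {
      warnf("group '%s' has zero classified loops", g)
      p <- c(NA_real_, NA_real_, NA_real_)
    } else {
      p <- c(n_conv, n_tand, n_div) / n_cls
    }
    data.frame(group = g, n_convergent = n_conv, n_tandem = n_tand,
               n_divergent = n_div, n_unclassified = n_un,
               p_convergent = p[1], p_tandem = p[2], p_divergent = p[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative placement of a cofactor motif with respect to a primary motif
#'
#' Positional reading: on the 5' anchor "inside" means the cofactor (e.g.
#' MAZ) motif midpoint lies loop-ward — at a greater coordinate — than the
#' primary (e.g. CTCF) motif midpoint; on the 3' anchor the relation is
#' mirrored. Ties are "outside". A strand-based variant instead calls
#' "inside" when the cofactor motif strand points into the loop (`'+'` on
#' the 5' anchor, `'-'` on the 3' anchor).
#'
#' @param primary_hit,cofactor_hit one-row hit data frames on the same
#'   anchor (same chromosome).
#' @param anchor_side `"5"` or `"3"`.
#' @param mode `"position"` (default) or `"strand"`.
#' @return `"inside"` or `"outside"`.
#' @export
relative_orientation <- function(primary_hit, cofactor_hit,
                                 anchor_side = c("5", "3"),
                                 mode = c("position", "strand")) {
  anchor_side <- match.arg(anchor_side)
  mode <- match.arg(mode)
  if (primary_hit$chrom != cofactor_hit$chrom)
    stopf("primary and cofactor hits on different chromosomes")
  if (mode == "strand") {
    loopward <- if (anchor_side == "5") "+" else "-"
    return(if (cofactor_hit$strand == loopward) "inside" else "outside")
  }
  pm <- interval_mid(primary_hit$start, primary_hit$end)
  cm <- interval_mid(cofactor_hit$start, cofactor_hit$end)
  inside <- if (anchor_side == "5") cm > pm else cm < pm
  if (inside) "inside" else "outside"
}

#' Motif spacing analysis around primary sites
#'
#' For each (deduplicated) primary motif hit, the window of `window_bp`
#' centered on its midpoint is extracted from the genome and scanned with
#' the secondary PWM; the best secondary hit's signed center-to-center
#' distance is recorded (positive = downstream in the primary motif's
#' `'+'` orientation, i.e. the sign is flipped for `'-'`-strand primaries).
#' Distances are histogrammed at `bin_width` and each bin is tested for
#' enrichment against a uniform-placement null with a one-sided binomial
#' test, BH-corrected across bins.
#'
#' @param primary_hits hit data frame (e.g. CTCF); overlapping primaries
#'   are deduplicated keeping the highest score.
#' @param secondary_pwm `pwm` of the cofactor motif (e.g. MAZ).
#' @param genome named character vector of chromosome sequences.
#' @param window_bp even window size in bp centered on the primary
#'   midpoint (default 500).
#' @param p_cutoff scan p-value cutoff for secondary hits (default 1e-3).
#' @param bin_width histogram bin width in bp (default 5).
#' @return list with `distances` (signed bp, one per primary site with a
#'   secondary hit), `histogram` (data frame `bin_lo`, `bin_hi`, `count`,
#'   `pvalue`, `fdr`), `n_sites`, `n_with_hit`, `n_skipped` (windows
#'   exceeding chromosome bounds).
#' @export
spacing_analysis <- function(primary_hits, secondary_pwm, genome,
                             window_bp = 500, p_cutoff = 1e-3,
                             bin_width = 5) {
  stopifnot(window_bp %% 2 == 0, window_bp > 0, bin_width > 0)
  # deduplicate overlapping primaries: keep highest score
  h <- primary_hits[order(primary_hits$chrom, primary_hits$start), ,
                    drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  if (nrow(h) > 1) {
    last_kept <- 1L
    for (i in 2L:nrow(h)) {
      if (h$chrom[i] == h$chrom[last_kept] &&
          h$start[i] < h$end[last_kept]) {
        if (h$score[i] > h$score[last_kept]) {
          keep[last_kept] <- FALSE
          last_kept <- i
        } else keep[i] <- FALSE
      } else last_kept <- i
    }
  }
  h <- h[keep, , drop = FALSE]
  half <- window_bp %/% 2
  dist_tab <- score_pvalue_table(secondary_pwm)
  view <- genome_view(genome)
  distances <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(h))) {
    chrom <- h$chrom[i]
    if (!chrom %in% names(view)) { n_skipped <- n_skipped + 1L; next }
    mid <- floor(interval_mid(h$start[i], h$end[i]))
    lo <- mid - half
    hi <- mid + half
    L <- length(view[[chrom]])
    if (lo < 0 || hi > L) { n_skipped <- n_skipped + 1L; next }
    win <- seq_window(view, chrom, lo, hi)
    sec <- suppressMessages(
      scan_sequence(secondary_pwm, win, chrom = chrom,
                    p_cutoff = p_cutoff, dist = dist_tab, offset0 = lo))
    if (nrow(sec) == 0) next
    best <- sec[order(-sec$score, sec$start, sec$strand)[1], , drop = FALSE]
    d <- interval_mid(best$start, best$end) - (h$start[i] + h$end[i]) / 2
    if (h$strand[i] == "-") d <- -d
    distances <- c(distances, d)
  }
  edges <- seq(-half, half, by = bin_width)
  if (edges[length(edges)] < half) edges <- c(edges, half)
  counts <- if (length(distances)) {
    hist(pmin(pmax(distances, -half), half - 1e-9), breaks = edges,
         plot = FALSE, right = FALSE)$counts
  } else rep(0L, length(edges) - 1L)
  n_with_hit <- length(distances)
  p0 <- bin_width / window_bp
  pvals <- if (n_with_hit > 0) {
    vapply(counts, function(x)
      stats::binom.test(x, n_with_hit, p0, alternative = "greater")$p.value,
      numeric(1))
  } else rep(1, length(counts))
  histogram <- data.frame(bin_lo = edges[-length(edges)],
                          bin_hi = edges[-1], count = counts,
                          pvalue = pvals,
                          fdr = stats::p.adjust(pvals, method = "BH"))
  list(distances = distances, histogram = histogram,
       n_sites = nrow(h), n_with_hit = n_with_hit, n_skipped = n_skipped)
}
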