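toy_loop <- function(chrom = "c", s5 = 0L, e5 = 5000L, s3 = 20000L,
                     e3 = 25000L) {
  data.frame(chrom = chrom, start5 = s5, end5 = e5, start3 = s3,
             end3 = e3, name = "L1",
             distance = (s3 + e3) / 2 - (s5 + e5) / 2,
             stringsAsFactors = FALSE)
}

test_that("anchor_search_regions intersects anchors with peaks", {
  loop <- toy_loop()
  peaks <- data.frame(chrom = "c", start = c(4000L, 1000L, 21000L, 23000L),
                      end = c(6000L, 2000L, 22000L, 24000L),
                      name = NA, signal = NA)
  peaks <- peaks[order(peaks$start), ]
  regs <- anchor_search_regions(loop[1, ], peaks)
  # anchor5 [0,5000) x peaks -> [1000,2000) and [4000,5000)
  expect_equal(regs$anchor5$start, c(1000L, 4000L))
  expect_equal(regs$anchor5$end, c(2000L, 5000L))
  # anchor3 [20000,25000) -> two disjoint regions
  expect_equal(nrow(regs$anchor3), 2L)
  # no overlap -> empty
  far <- data.frame(chrom = "c", start = 90000L, end = 99000L,
                    name = NA, signal = NA)
  expect_equal(nrow(anchor_search_regions(loop[1, ], far)$anchor5), 0L)
})

test_that("filter_loops_by_signal applies the binary both-anchor rule", {
  loops <- rbind(toy_loop(), toy_loop(s5 = 40000L, e5 = 45000L,
                                      s3 = 80000L, e3 = 85000L))
  peaks <- data.frame(chrom = "c",
                      start = c(1000L, 21000L, 41000L, 81000L),
                      end = c(2000L, 22000L, 42000L, 82000L),
                      name = NA,
                      signal = c(10, 10, 10, 2))
  # cutoff 0 keeps everything
  expect_equal(nrow(suppressMessages(
    filter_loops_by_signal(loops, list(CTCF = peaks), c(CTCF = 0)))), 2L)
  # cutoff 5: loop 2 has one anchor at signal 2 -> removed
  kept <- suppressMessages(
    filter_loops_by_signal(loops, list(CTCF = peaks), c(CTCF = 5)))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start5, 0L)
  # missing track errors
  expect_error(filter_loops_by_signal(loops, list(), c(CTCF = 1)),
               "no peak track")
})

test_that("filter_loops_by_signal matches a brute-force oracle on random data", {
  set.seed(21)
  n <- 60
  s5 <- sort(sample.int(1e6, n)) * 10L
  loops <- data.frame(chrom = "c", start5 = s5, end5 = s5 + 5000L,
                      start3 = s5 + 200000L, end3 = s5 + 205000L,
                      name = sprintf("L%d", 1:n),
                      distance = 200000)
  # one peak per anchor with random signal
  mk <- function(starts) data.frame(chrom = "c", start = starts + 100L,
                                    end = starts + 400L, name = NA,
                                    signal = runif(length(starts), 0, 10))
  peaks <- rbind(mk(loops$start5), mk(loops$start3))
  peaks <- peaks[order(peaks$start), ]
  cutoff <- 4
  kept <- suppressMessages(
    filter_loops_by_signal(loops, list(F = peaks), c(F = cutoff)))
  # oracle: per loop, max overlapping-peak signal per anchor
  oracle_keep <- vapply(seq_len(n), function(i) {
    sig <- function(a, b) {
      o <- peaks$signal[peaks$start < b & peaks$end > a]
      if (length(o)) max(o) else 0
    }
    sig(loops$start5[i], loops$end5[i]) >= cutoff &&
      sig(loops$start3[i], loops$end3[i]) >= cutoff
  }, logical(1))
  expect_equal(kept$name, loops$name[oracle_keep])
})

test_that("assign_anchor_motifs honors peak restriction and best-hit rule", {
  loop <- toy_loop()
  peaks <- data.frame(chrom = "c", start = c(1000L, 21000L),
                      end = c(2000L, 22000L), name = NA, signal = NA)
  hits <- data.frame(chrom = "c",
                     start = c(1100L, 1200L, 3000L, 21500L),
                     end = c(1119L, 1219L, 3019L, 21519L),
                     strand = c("+", "-", "-", "-"),
                     score = c(5, 9, 30, 7), pvalue = 1e-4)
  ann <- assign_anchor_motifs(loop, list(CTCF = hits), list(CTCF = peaks))
  # the 30-score hit is inside the anchor but outside every peak: ignored
  expect_equal(ann$score5, 9)
  expect_equal(ann$strand5, "-")
  expect_equal(ann$strand3, "-")
  # p_cutoff filter drops weak-p hits
  hits$pvalue <- c(1e-4, 0.5, 1e-4, 1e-4)
  ann2 <- assign_anchor_motifs(loop, list(CTCF = hits), list(CTCF = peaks))
  expect_equal(ann2$score5, 5)
})

test_that("orientation classification implements the strand grammar", {
  expect_equal(classify_orientation("+", "-"), "convergent")
  expect_equal(classify_orientation("-", "+"), "divergent")
  expect_equal(classify_orientation("+", "+"), "tandem")
  expect_equal(classify_orientation("-", "-"), "tandem")
  expect_equal(classify_orientation("+", NA), "unclassified")
  expect_equal(classify_orientation(NA, NA), "unclassified")
  # pure function of the strands: vectorized, order-independent
  s5 <- c("+", "-", "+", NA)
  s3 <- c("-", "+", "+", "-")
  calls <- classify_orientation(s5, s3)
  perm <- c(3, 1, 4, 2)
  expect_equal(classify_orientation(s5[perm], s3[perm]), calls[perm])
})

test_that("orientation proportions exclude unclassified and sum to one", {
  calls <- c("convergent", "convergent", "tandem", "divergent",
             "unclassified")
  pr <- orientation_proportions(calls)
  expect_equal(pr$p_convergent, 0.5)
  expect_equal(pr$p_tandem, 0.25)
  expect_equal(pr$p_divergent, 0.25)
  expect_equal(pr$n_unclassified, 1L)
  expect_equal(pr$p_convergent + pr$p_tandem + pr$p_divergent, 1,
               tolerance = 1e-12)
  # group with zero classified loops is flagged
  expect_warning(pr2 <- orientation_proportions(c("unclassified",
                                                  "unclassified")),
                 "zero classified")
  expect_true(is.na(pr2$p_convergent))
})

test_that("relative_orientation mirrors between anchors and breaks ties outside", {
  ctcf <- data.frame(chrom = "c", start = 990L, end = 1010L, strand = "+",
                     score = 10, pvalue = 1e-5)
  maz_in <- data.frame(chrom = "c", start = 1070L, end = 1090L,
                       strand = "+", score = 8, pvalue = 1e-4)
  expect_equal(relative_orientation(ctcf, maz_in, "5"), "inside")
  expect_equal(relative_orientation(ctcf, maz_in, "3"), "outside")
  # identical midpoints -> outside
  expect_equal(relative_orientation(ctcf, ctcf, "5"), "outside")
  # strand-based variant: loop-ward strand on the 3' anchor is '-'
  expect_equal(relative_orientation(ctcf, maz_in, "3", mode = "strand"),
               "outside")
  maz_neg <- transform(maz_in, strand = "-")
  expect_equal(relative_orientation(ctcf, maz_neg, "3", mode = "strand"),
               "inside")
  # cross-chromosome pairs are rejected
  expect_error(relative_orientation(ctcf, transform(maz_in, chrom = "d"),
                                    "5"), "different chrom")
})

test_that("spacing_analysis recovers a planted offset", {
  set.seed(5)
  # genome with 60 CTCF sites; MAZ planted at +85 bp for most
  cfg <- scenario_config(seed = 5, chrom_size = 2e6, n_loops = 0L,
                         tad_size_bp = NULL, n_spacing_sites = 60L,
                         maz_offset_rate = 0.8, spacing_offset = 85)
  scn <- simulate_scenario(cfg, contact_maps = FALSE)
  hits <- scan_peak_regions(cfg$ctcf_pwm, scn$genome, scn$peaks$CTCF)
  sp <- spacing_analysis(hits, cfg$maz_pwm, scn$genome)
  mode_bin <- sp$histogram[which.max(sp$histogram$count), ]
  expect_true(mode_bin$bin_lo <= 85 && mode_bin$bin_hi > 85)
  expect_lt(min(sp$histogram$fdr), 0.05)
  # signed distances concentrate near +85 regardless of site strand
  expect_gt(mean(abs(sp$distances - 85) < 5), 0.5)
})

test_that("spacing_analysis with no secondary hits yields an all-null histogram", {
  hits <- data.frame(chrom = "g", start = 500L, end = 519L, strand = "+",
                     score = 10, pvalue = 1e-5)
  genome <- c(g = paste(rep("AT", 1000), collapse = ""))
  sp <- spacing_analysis(hits, pwm_from_consensus("GGGAGGG"), genome)
  expect_equal(sp$n_with_hit, 0L)
  expect_equal(sum(sp$histogram$count), 0L)
  expect_true(all(sp$histogram$pvalue == 1))
})

test_that("spacing windows beyond chromosome bounds are skipped and counted", {
  hits <- data.frame(chrom = "g", start = c(10L, 900L), end = c(29L, 919L),
                     strand = "+", score = 10, pvalue = 1e-5)
  genome <- c(g = random_seq(1800))
  sp <- spacing_analysis(hits, pwm_from_consensus("GGGAGGG"), genome)
  expect_equal(sp$n_skipped, 1L)
  expect_equal(sp$n_sites, 2L)
})
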