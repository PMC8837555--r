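sym_rpois_matrix <- function(n, lambda = 5) {
  M <- matrix(0, n, n)
  ut <- upper.tri(M, diag = TRUE)
  M[ut] <- rpois(sum(ut), lambda)
  M + t(M) - diag(diag(M))
}

test_that("bin_contacts applies the distance filter and symmetrizes", {
  pairs <- data.frame(chrom = "c",
                      pos1 = c(100000, 0, 10000),
                      pos2 = c(110000, 50000, 800000))
  cm <- bin_contacts(pairs, "c", 1e6)
  # (100000,110000) dropped: distance 10 kb < 25 kb
  expect_equal(sum(cm$counts), 4)   # two kept pairs, each mirrored
  expect_equal(cm$counts[1, 3], 1)  # (0, 50000) -> bins 0 and 2
  expect_equal(cm$counts[3, 1], 1)
  expect_equal(cm$counts[1, 41], 1) # (10000, 800000)
  expect_error(bin_contacts(data.frame(chrom = "c", pos1 = -5, pos2 = 100),
                            "c", 1e6), "negative")
})

test_that("bin_contacts retained count matches a brute-force filter", {
  set.seed(3)
  pairs <- data.frame(chrom = "c",
                      pos1 = sample.int(1e6, 500) - 1,
                      pos2 = sample.int(1e6, 500) - 1)
  cm <- bin_contacts(pairs, "c", 1e6)
  oracle <- sum(abs(pairs$pos2 - pairs$pos1) >= 25000)
  # each retained off-diagonal pair contributes 2; same-bin pairs 1
  kept <- pairs[abs(pairs$pos2 - pairs$pos1) >= 25000, ]
  same_bin <- sum(kept$pos1 %/% 20000 == kept$pos2 %/% 20000)
  expect_equal(sum(cm$counts), 2 * oracle - same_bin)
})

test_that("ICE balancing fixes constant matrices and masks empty bins", {
  M <- matrix(1, 8, 8)
  cm <- ice_balance(contact_matrix("c", 10, M), mask_fraction = 0)
  expect_equal(max(abs(cm$biases / cm$biases[1] - 1)), 0, tolerance = 1e-9)
  rs <- rowSums(cm$balanced)
  expect_equal(max(abs(rs / mean(rs) - 1)), 0, tolerance = 1e-6)

  M2 <- sym_rpois_matrix(10, 8)
  M2[4, ] <- 0
  M2[, 4] <- 0
  cm2 <- ice_balance(contact_matrix("c", 10, M2), mask_fraction = 0)
  expect_true(cm2$mask[4])
  expect_true(all(is.na(cm2$balanced[4, ])))
  rs2 <- rowSums(cm2$balanced[!cm2$mask, !cm2$mask])
  expect_lt(max(abs(rs2 / mean(rs2) - 1)), 1e-6)
})

test_that("ICE matches the alternating-normalization oracle on 6x6 matrices", {
  set.seed(17)
  for (rep in 1:5) {
    M <- sym_rpois_matrix(6, 20) + 1  # strictly positive
    cm <- ice_balance(contact_matrix("c", 10, M), mask_fraction = 0,
                      tol = 1e-12, max_iter = 5000)
    mine <- cm$balanced / rowSums(cm$balanced)
    oracle <- sinkhorn_oracle(M)
    expect_lt(max(abs(mine - oracle)), 1e-6)
  }
})

test_that("ICE balancing is idempotent", {
  set.seed(23)
  M <- sym_rpois_matrix(30, 10)
  cm <- ice_balance(contact_matrix("c", 10, M))
  bal <- ifelse(is.na(cm$balanced), 0, cm$balanced)
  cm2 <- ice_balance(contact_matrix("c", 10, bal), mask_fraction = 0)
  ok <- !cm2$mask
  expect_lt(max(abs(cm2$biases[ok] / mean(cm2$biases[ok]) - 1)), 1e-4)
})

test_that("expected_by_distance recovers flat and power-law profiles", {
  cm <- contact_matrix("c", 10, matrix(2, 10, 10))
  expect_equal(expected_by_distance(cm), rep(2, 10))

  # planted alpha = 1 decay: log-log slope of the profile ~ -1
  set.seed(31)
  n <- 200
  E <- decay_matrix(n, depth = 5e5)$counts
  obs <- matrix(0, n, n)
  ut <- upper.tri(E, diag = TRUE)
  obs[ut] <- rpois(sum(ut), E[ut])
  obs <- obs + t(obs) - diag(diag(obs))
  prof <- expected_by_distance(contact_matrix("c", 20000, obs))
  d <- 1:80
  fit <- lm(log(prof[d + 1]) ~ log(d + 1))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  # diagonal mean is the first element
  expect_equal(prof[1], mean(diag(obs)))
})

test_that("APA of a constant matrix is flat 1 after O/E and P2LL identities hold", {
  n <- 60
  cm <- contact_matrix("c", 5000, matrix(3, n, n))
  loops <- data.frame(chrom = "c", start5 = 10 * 5000, end5 = 11 * 5000,
                      start3 = 45 * 5000, end3 = 46 * 5000, name = "L",
                      distance = 35 * 5000)
  res <- apa(cm, loops, resolution = 5000)
  expect_equal(res$n_loops_used, 1L)
  expect_equal(max(abs(res$aggregate - 1)), 0, tolerance = 1e-12)
  expect_equal(res$p2ll, 1)

  agg <- matrix(1, 21, 21)
  agg[11, 11] <- 5
  expect_equal(p2ll(agg), 5)
  # linear in the center holding the corner fixed
  agg[11, 11] <- 10
  expect_equal(p2ll(agg), 10)
  expect_error(p2ll(matrix(0, 21, 21)), "corner mean")
})

test_that("APA skips near-diagonal and edge loops, errors when none usable", {
  n <- 50
  cm <- contact_matrix("c", 5000, matrix(1, n, n))
  near <- data.frame(chrom = "c", start5 = 20 * 5000, end5 = 21 * 5000,
                     start3 = 25 * 5000, end3 = 26 * 5000, name = "near",
                     distance = 5 * 5000)
  expect_error(apa(cm, near, resolution = 5000), "no loops")
  expect_error(apa(cm, near, resolution = 10000), "resolution")
})

test_that("APA is translation invariant", {
  set.seed(41)
  n <- 120
  M <- sym_rpois_matrix(n, 4)
  shift <- 7L
  # embed the same matrix shifted by `shift` bins in a larger frame
  n2 <- n + shift
  M2 <- matrix(0, n2, n2)
  M2[(shift + 1):n2, (shift + 1):n2] <- M
  loops <- data.frame(chrom = "c",
                      start5 = c(20, 40) * 5000, end5 = c(21, 41) * 5000,
                      start3 = c(80, 95) * 5000, end3 = c(81, 96) * 5000,
                      name = c("a", "b"), distance = 0)
  loops2 <- transform(loops, start5 = start5 + shift * 5000,
                      end5 = end5 + shift * 5000,
                      start3 = start3 + shift * 5000,
                      end3 = end3 + shift * 5000)
  r1 <- apa(contact_matrix("c", 5000, M), loops, resolution = 5000,
            normalize = "raw")
  r2 <- apa(contact_matrix("c", 5000, M2), loops2, resolution = 5000,
            normalize = "raw")
  expect_equal(r1$aggregate, r2$aggregate)
})

test_that("loop distance histogram reports the sub-2Mb fraction", {
  loops <- data.frame(distance = c(1e6, 1e6, 3e6))
  got <- loop_distance_histogram(loops)
  expect_equal(got$fraction_below, 2 / 3)
  expect_warning(empty <- loop_distance_histogram(data.frame(distance =
                                                               numeric())),
                 "no loops")
  expect_true(is.na(empty$fraction_below))
})

test_that("sampled loop distances recover the generating fraction", {
  set.seed(51)
  d <- rlnorm(2000, log(6e5), 0.9)
  truth <- plnorm(2e6, log(6e5), 0.9)
  got <- loop_distance_histogram(data.frame(distance = d))
  expect_equal(got$fraction_below, truth, tolerance = 0.03)
})

test_that("boundary score vanishes at perfect block junctions and is flat on constant matrices", {
  # two perfect blocks with zero cross contacts
  n <- 40
  M <- matrix(0, n, n)
  M[1:20, 1:20] <- 5
  M[21:40, 21:40] <- 5
  cm <- contact_matrix("c", 10000, M)
  bt <- boundary_score(cm, window_bp = 50000)
  expect_equal(bt$scores[21], 0)  # junction bin: numerator vanishes

  cmc <- contact_matrix("c", 10000, matrix(2, n, n))
  btc <- boundary_score(cmc, window_bp = 50000)
  inner <- btc$scores[!is.na(btc$scores)]
  expect_equal(max(inner) - min(inner), 0, tolerance = 1e-12)
  expect_equal(length(call_boundaries(btc)), 0L)
  expect_error(boundary_score(cmc, window_bp = 75000), "multiple")
  expect_error(boundary_score(cmc, window_bp = 400000), "larger")
})

test_that("a single deep minimum yields one boundary and two TADs", {
  n <- 60
  scores <- rep(1, n)
  scores[c(1:5, 56:60)] <- NA
  scores[30] <- 0.2
  # tiny jitter so the SD is nonzero but the minimum dominates
  set.seed(9)
  scores[6:55] <- scores[6:55] + rnorm(50, 0, 0.01)
  scores[30] <- 0.2
  track <- structure(list(chrom = "c", bin_size = 10000,
                          window_bp = 50000, scores = scores),
                     class = "boundary_track")
  b <- call_boundaries(track, z_cutoff = 2)
  expect_equal(b, 29L)
  tads <- tads_from_boundaries(b, n, 10000, "c")
  expect_equal(nrow(tads), 2L)
  expect_equal(tads$bin_lo, c(0L, 29L))
  expect_equal(tads$bin_hi, c(29L, 60L))
  # flat track: single TAD spanning the chromosome
  tads0 <- tads_from_boundaries(integer(0), n, 10000, "c")
  expect_equal(nrow(tads0), 1L)
  expect_equal(tads0$end, n * 10000)
})

test_that("planted TAD boundaries are recovered within one bin", {
  cfg <- scenario_config(seed = 13, chrom_size = 1e7, n_loops = 0L,
                         tad_size_bp = c(4e5, 1.2e6),
                         tad_enrichment = 2.5, depth = 2e6,
                         chrom = "chrB")
  scn <- simulate_scenario(cfg, contact_maps = TRUE)
  pool <- contact_matrix("chrB", cfg$bin_size,
                         scn$maps$wt[[1]]$counts + scn$maps$wt[[2]]$counts)
  bal <- ice_balance(pool)
  bt <- boundary_score(bal, window_bp = 500000)
  called <- call_boundaries(bt)
  truth <- scn$truth$tad_boundaries
  W <- 500000 / cfg$bin_size
  scorable <- truth[truth > W & truth < bal$n_bins - W]
  hit <- vapply(scorable, function(b) any(abs(called - b) <= 1),
                logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("intra-TAD activity is 1 at expectation and scales with enrichment", {
  n <- 80
  E <- decay_matrix(n)$counts
  cm <- contact_matrix("c", 20000, E)
  tads <- data.frame(chrom = "c", start = c(0, 40) * 20000,
                     end = c(40, 80) * 20000, bin_lo = c(0L, 40L),
                     bin_hi = c(40L, 80L))
  act <- intra_tad_activity(cm, tads)
  expect_equal(act$activity, c(1, 1), tolerance = 1e-9)

  # doubling intra-TAD pixels of TAD 1 doubles its activity measure
  E2 <- E
  E2[1:40, 1:40] <- E2[1:40, 1:40] * 2
  cm2 <- contact_matrix("c", 20000, E2)
  act2 <- intra_tad_activity(cm2, tads, expected = expected_by_distance(cm))
  expect_equal(act2$activity[1], 2, tolerance = 1e-9)
  # sub-3-bin TADs are flagged
  small <- data.frame(chrom = "c", start = 0, end = 40000,
                      bin_lo = 0L, bin_hi = 2L)
  expect_true(intra_tad_activity(cm, small)$flag_small)
})

test_that("differential activity: identical conditions give zero log2FC", {
  set.seed(61)
  counts <- matrix(rpois(200, 50), 100, 2)
  res <- differential_activity(counts, counts)
  expect_true(all(res$log2fc == 0))
  expect_false(any(res$significant))
})

test_that("differential activity applies both FDR and fold-change cutoffs", {
  # one strongly changed feature among flat ones
  set.seed(62)
  ca <- matrix(rpois(400, 40), 200, 2)
  cb <- ca
  cb[1, ] <- rpois(2, 400)
  res <- differential_activity(ca, cb, fdr_cutoff = 0.005,
                               lfc_cutoff = 1.5,
                               lib_sizes_a = rep(1e6, 2),
                               lib_sizes_b = rep(1e6, 2))
  expect_true(res$significant[1])
  expect_equal(sum(res$significant), 1L)
  # a feature whose FDR is 0.01 misses the 0.005 loop threshold by
  # construction of the cutoff comparison
  expect_false(any(res$fdr > 0.005 & res$significant))
  expect_error(differential_activity(matrix(0, 3, 2), matrix(1, 3, 2)),
               "zero total")
})

test_that("label swap negates log2FC and preserves p-values", {
  set.seed(63)
  ca <- matrix(rpois(300, 30), 150, 2)
  cb <- matrix(rpois(300, 45), 150, 2)
  fwd <- differential_activity(ca, cb)
  rev <- differential_activity(cb, ca)
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-12)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-12)
})

test_that("simple loop caller is calibrated on null matrices and finds planted pixels", {
  set.seed(71)
  n <- 150
  nulls <- 0L
  for (rep in 1:10) {
    E <- decay_matrix(n, depth = 3e5)$counts
    obs <- matrix(0, n, n)
    ut <- upper.tri(E, diag = TRUE)
    obs[ut] <- rpois(sum(ut), E[ut])
    obs <- obs + t(obs) - diag(diag(obs))
    calls <- simple_loop_call(contact_matrix("c", 20000, obs),
                              fdr_cutoff = 0.05)
    if (nrow(calls) == 0) nulls <- nulls + 1L
  }
  expect_gte(nulls, 9L)

  # a single 10x pixel with ample depth is recovered exactly
  E <- decay_matrix(n, depth = 3e5)$counts
  E[40, 90] <- E[40, 90] * 10
  E[90, 40] <- E[40, 90]
  obs <- matrix(0, n, n)
  ut <- upper.tri(E, diag = TRUE)
  set.seed(72)
  obs[ut] <- rpois(sum(ut), E[ut])
  obs <- obs + t(obs) - diag(diag(obs))
  calls <- simple_loop_call(contact_matrix("c", 20000, obs),
                            fdr_cutoff = 0.05)
  expect_true(any(calls$start5 == 39 * 20000 & calls$start3 == 89 * 20000))

  expect_error(simple_loop_call(contact_matrix("c", 10,
                                               matrix(0, 5, 5))),
               "empty")
})
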