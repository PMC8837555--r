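# Ground-truth scenario generator.
#
# Every synthetic scenario is drawn from a single seeded random stream in a
# fixed order (loops -> TAD boundaries -> genome -> motif offsets -> peaks
# -> contact maps), so a fixed seed reproduces the whole scenario exactly.
# The generator emulates the statistical structure the analyses assume:
# background sequence with planted CTCF/MAZ motif instances whose strands
# encode each loop's orientation class, ChIP-like peaks around the planted
# instances, a loop-distance law concentrated below 2 Mb, and
# Poisson-sampled contact maps with power-law distance decay, block-TAD
# enrichment and corner-peak loop enrichment.

#' Scenario configuration
#'
#' Bundles every tunable of the synthetic generator. Defaults mirror the
#' analysis conventions: 20-kb matrix bins, a loop-distance law with ~90%
#' of loops under 2 Mb, a cofactor (MAZ) motif offset of 70-140 bp from
#' the primary (CTCF) motif, TADs of 0.4-1.2 Mb with 2.5x intra
#' enrichment, 3x loop corner enrichment, and a knockout condition that
#' attenuates 30% of loops 4-fold.
#'
#' @param seed integer seed for the scenario stream.
#' @param chrom chromosome name.
#' @param chrom_size chromosome length in bp.
#' @param gc GC fraction of the background sequence.
#' @param bin_size contact-matrix bin size in bp.
#' @param n_loops number of planted loops.
#' @param mixture length-3 class mixture `(convergent, tandem, divergent)`
#'   summing to 1.
#' @param dist_meanlog,dist_sdlog lognormal parameters of the loop
#'   anchor-distance law in bp.
#' @param dist_min minimum anchor distance in bp.
#' @param ctcf_pwm,maz_pwm `pwm` objects planted and scanned.
#' @param maz_offset_bp length-2 range of the MAZ-to-CTCF center offset in
#'   bp (drawn uniformly; `NULL` plants no MAZ).
#' @param maz_offset_rate fraction of CTCF instances that receive a MAZ
#'   instance.
#' @param peak_width_bp ChIP-like peak width.
#' @param peak_signal_mean mean peak signal (log-normal).
#' @param decoy_peak_rate decoy peaks (no planted motif) per true peak.
#' @param alpha power-law distance-decay exponent.
#' @param tad_size_bp length-2 range of TAD sizes in bp (`NULL` plants no
#'   TADs).
#' @param tad_enrichment intra-TAD contact multiplier (>= 1).
#' @param loop_enrichment loop-pixel contact multiplier (>= 1), with a
#'   1-bin halo at half strength.
#' @param depth expected read pairs per replicate.
#' @param n_replicates replicates per condition.
#' @param ko_fraction fraction of loops attenuated in the KO condition.
#' @param ko_attenuation multiplier applied to every loop-associated pixel
#'   factor of an attenuated loop (KO/WT expected ratio at those pixels).
#' @param n_spacing_sites standalone primary (CTCF) sites for spacing-only
#'   scenarios (planted independently of loops).
#' @param spacing_offset either a length-2 range (uniform draw) or a
#'   single value for the planted MAZ offset at spacing sites; `"uniform"`
#'   places MAZ uniformly in the 500-bp window (null placement).
#' @return object of class `scenario_config` (a list).
#' @export
scenario_config <- function(seed = 1L,
                            chrom = "chrS",
                            chrom_size = 4e7,
                            gc = 0.42,
                            bin_size = 20000,
                            n_loops = 300L,
                            mixture = c(convergent = 0.60, tandem = 0.30,
                                        divergent = 0.10),
                            dist_meanlog = log(6e5),
                            dist_sdlog = 0.9,
                            dist_min = 1e5,
                            ctcf_pwm = NULL,
                            maz_pwm = NULL,
                            maz_offset_bp = c(70, 140),
                            maz_offset_rate = 1.0,
                            peak_width_bp = 200L,
                            peak_signal_mean = 10,
                            decoy_peak_rate = 0,
                            alpha = 1.0,
                            tad_size_bp = c(4e5, 1.2e6),
                            tad_enrichment = 2.5,
                            loop_enrichment = 3.0,
                            depth = 1e6,
                            n_replicates = 2L,
                            ko_fraction = 0.3,
                            ko_attenuation = 0.25,
                            n_spacing_sites = 0L,
                            spacing_offset = c(70, 140)) {
  if (is.null(ctcf_pwm)) ctcf_pwm <- default_ctcf_pwm()
  if (is.null(maz_pwm)) maz_pwm <- default_maz_pwm()
  stopifnot(abs(sum(mixture) - 1) < 1e-9, tad_enrichment >= 1,
            loop_enrichment >= 1, depth > 0, gc > 0, gc < 1)
  structure(list(seed = as.integer(seed), chrom = chrom,
                 chrom_size = chrom_size, gc = gc, bin_size = bin_size,
                 n_loops = as.integer(n_loops), mixture = mixture,
                 dist_meanlog = dist_meanlog, dist_sdlog = dist_sdlog,
                 dist_min = dist_min, ctcf_pwm = ctcf_pwm,
                 maz_pwm = maz_pwm, maz_offset_bp = maz_offset_bp,
                 maz_offset_rate = maz_offset_rate,
                 peak_width_bp = as.integer(peak_width_bp),
                 peak_signal_mean = peak_signal_mean,
                 decoy_peak_rate = decoy_peak_rate, alpha = alpha,
                 tad_size_bp = tad_size_bp,
                 tad_enrichment = tad_enrichment,
                 loop_enrichment = loop_enrichment, depth = depth,
                 n_replicates = as.integer(n_replicates),
                 ko_fraction = ko_fraction,
                 ko_attenuation = ko_attenuation,
                 n_spacing_sites = as.integer(n_spacing_sites),
                 spacing_offset = spacing_offset),
            class = "scenario_config")
}

#' Default CTCF-like PWM (synthetic)
#'
#' A sharp 19-position PWM over a CTCF-like core consensus, built with
#' [pwm_from_consensus()]. This is a synthetic stand-in used by the
#' generator and tests; analyses accept any user-supplied PWM.
#'
#' @return a `pwm`.
#' @export
default_ctcf_pwm <- function() {
  pwm_from_consensus("TGGCCACCAGGGGGCGCTA", name = "CTCF_synthetic")
}

#' Default MAZ-like PWM (synthetic)
#'
#' Sharp PWM over the GGGAGGG GC-box consensus that MAZ binds.
#'
#' @return a `pwm`.
#' @export
default_maz_pwm <- function() {
  pwm_from_consensus("GGGAGGG", name = "MAZ_synthetic")
}

#' Scenario presets
#'
#' * `"maz_ko_like"`: the full default scenario — planted loops with a
#'   (0.60, 0.30, 0.10) convergent/tandem/divergent mixture, MAZ offsets
#'   of 70-140 bp from CTCF, TADs, and a KO condition attenuating 30% of
#'   loops 4-fold.
#' * `"null"`: no loops, no TADs, pure decay background.
#' * `"spacing_only"`: 500 standalone CTCF sites with MAZ planted at
#'   +85 bp for 70% of them; no loops, no matrices needed.
#'
#' @param name preset name.
#' @param seed scenario seed.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(name = c("maz_ko_like", "null",
                                     "spacing_only"), seed = 1L) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("maz_ko_like", "null", "spacing_only"))
    stopf("unknown preset '%s'; available: maz_ko_like, null, spacing_only",
          paste(name, collapse = ","))
  switch(name,
         maz_ko_like = scenario_config(seed = seed),
         null = scenario_config(seed = seed, n_loops = 0L,
                                tad_size_bp = NULL, chrom_size = 1e7),
         spacing_only = scenario_config(seed = seed, n_loops = 0L,
                                        tad_size_bp = NULL,
                                        chrom_size = 2e7,
                                        n_spacing_sites = 500L,
                                        maz_offset_rate = 0.7,
                                        spacing_offset = 85))
}

# draw TAD boundaries tiling [0, n_bins) from the configured size law
draw_tad_boundaries <- function(config) {
  if (is.null(config$tad_size_bp)) return(integer(0))
  b <- integer(0)
  pos <- 0
  repeat {
    size <- stats::runif(1, config$tad_size_bp[1], config$tad_size_bp[2])
    pos <- pos + round(size / config$bin_size)
    if (pos * config$bin_size >= config$chrom_size) break
    b <- c(b, as.integer(pos))
  }
  b
}

#' Plant loops with orientation classes
#'
#' Anchor midpoints are snapped to bin centers, classes drawn i.i.d. from
#' the mixture, anchor distances from a truncated lognormal, and no two
#' loops may share an anchor bin (colliding draws are redrawn). Anchors
#' are one bin wide.
#'
#' @param config a [scenario_config()]. Uses the current RNG stream; seed
#'   it (or use [simulate_scenario()]) for reproducibility.
#' @return list with `loops` (loop data frame) and `classes` (character
#'   vector), also stored in the truth table by [simulate_scenario()].
#' @export
make_loops <- function(config) {
  n <- config$n_loops
  bs <- config$bin_size
  n_bins <- floor(config$chrom_size / bs)
  if (n == 0) {
    return(list(loops = data.frame(chrom = character(), start5 = integer(),
                                   end5 = integer(), start3 = integer(),
                                   end3 = integer(), name = character(),
                                   distance = numeric()),
                classes = character(0)))
  }
  used_bins <- logical(n_bins)
  b5 <- integer(n)
  b3 <- integer(n)
  max_try <- 200L * n
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > max_try)
      stopf("chromosome too small for %d non-overlapping loops", n)
    d <- stats::rlnorm(1, config$dist_meanlog, config$dist_sdlog)
    d <- max(d, config$dist_min)
    dbins <- max(1L, as.integer(round(d / bs)))
    if (dbins >= n_bins - 2L) next
    a <- sample.int(n_bins - dbins, 1L)
    b <- a + dbins
    if (used_bins[a] || used_bins[b]) next
    used_bins[a] <- used_bins[b] <- TRUE
    b5[i] <- a
    b3[i] <- b
    i <- i + 1L
  }
  classes <- sample(names(config$mixture), n, replace = TRUE,
                    prob = config$mixture)
  loops <- data.frame(chrom = config$chrom,
                      start5 = (b5 - 1L) * bs, end5 = b5 * bs,
                      start3 = (b3 - 1L) * bs, end3 = b3 * bs,
                      name = sprintf("loop_%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
  loops$distance <- (b3 - b5) * bs
  ord <- order(loops$start5, loops$start3)
  list(loops = loops[ord, , drop = FALSE], classes = classes[ord])
}

# strand pair for a loop class; tandem flips a fair coin between ++ and --
class_strands <- function(classes) {
  t(vapply(classes, function(cl) {
    switch(cl,
           convergent = c("+", "-"),
           divergent = c("-", "+"),
           tandem = if (stats::runif(1) < 0.5) c("+", "+") else c("-", "-"),
           stopf("unknown loop class '%s'", cl))
  }, character(2)))
}

#' Generate a background genome with planted motif instances
#'
#' Background bases are i.i.d. at the configured GC fraction. A CTCF
#' consensus instance is planted at the center of each loop anchor with
#' the strand dictated by the loop's class, and a MAZ consensus instance
#' at a signed offset from the CTCF midpoint (drawn from
#' `config$maz_offset_bp`, oriented by the CTCF strand, MAZ co-oriented
#' with CTCF). Standalone spacing sites (if configured) are planted the
#' same way. Overlapping placements are redrawn a bounded number of times.
#'
#' @param config a [scenario_config()].
#' @param loops loop data frame from [make_loops()] (or `NULL`).
#' @param classes loop class labels matching `loops`.
#' @return list with `genome` (named character vector) and `motifs` (truth
#'   data frame: `factor`, `chrom`, `start`, `strand`, `site` identifier).
#' @export
make_genome <- function(config, loops = NULL, classes = NULL) {
  L <- as.integer(config$chrom_size)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  base_codes <- utf8ToInt("ACGT")
  codes <- base_codes[sample.int(4L, L, replace = TRUE, prob = p)]
  ctcf_cons <- pwm_consensus(config$ctcf_pwm)
  maz_cons <- pwm_consensus(config$maz_pwm)
  Kc <- nchar(ctcf_cons)
  Km <- nchar(maz_cons)
  # placements are collected first (overlap checks against the small list
  # of already-planted intervals) and written into the sequence in one
  # pass at the end
  env <- new.env(parent = emptyenv())
  env$starts <- integer(0)
  env$ends <- integer(0)
  env$motifs <- vector("list", 0)
  env$words <- character(0)
  occupied <- function(start, len) {
    any(env$starts < start + len & env$ends > start)
  }
  add_plant <- function(factor, word, start, strand, site_id) {
    env$starts <- c(env$starts, start)
    env$ends <- c(env$ends, start + nchar(word))
    env$words <- c(env$words, if (strand == "-") revcomp(word) else word)
    env$motifs[[length(env$motifs) + 1L]] <-
      data.frame(factor = factor, chrom = config$chrom, start = start,
                 strand = strand, site = site_id, stringsAsFactors = FALSE)
  }
  plant_site <- function(center, strand, site_id, maz_mode) {
    # center = CTCF midpoint (bp)
    cstart <- as.integer(round(center - Kc / 2))
    if (cstart < 0 || cstart + Kc > L) return(FALSE)
    if (occupied(cstart, Kc)) return(FALSE)
    add_plant("CTCF", ctcf_cons, cstart, strand, site_id)
    if (!is.null(maz_mode)) {
      off <- maz_mode()
      if (!is.null(off)) {
        dir <- if (strand == "+") 1 else -1
        mmid <- center + dir * off
        mstart <- as.integer(round(mmid - Km / 2))
        if (mstart >= 0 && mstart + Km <= L && !occupied(mstart, Km)) {
          add_plant("MAZ", maz_cons, mstart, strand, site_id)
        }
      }
    }
    TRUE
  }
  loop_maz <- function() {
    if (is.null(config$maz_offset_bp)) return(NULL)
    if (stats::runif(1) > config$maz_offset_rate) return(NULL)
    stats::runif(1, config$maz_offset_bp[1], config$maz_offset_bp[2])
  }
  if (!is.null(loops) && nrow(loops)) {
    strands <- class_strands(classes)
    for (i in seq_len(nrow(loops))) {
      ok <- plant_site((loops$start5[i] + loops$end5[i]) / 2, strands[i, 1],
                       sprintf("%s_a5", loops$name[i]), loop_maz)
      ok <- ok && plant_site((loops$start3[i] + loops$end3[i]) / 2,
                             strands[i, 2],
                             sprintf("%s_a3", loops$name[i]), loop_maz)
      if (!ok) stopf("could not plant motifs for loop %s", loops$name[i])
    }
  }
  if (config$n_spacing_sites > 0) {
    half_win <- 250
    spacing_maz <- function() {
      if (stats::runif(1) > config$maz_offset_rate) return(NULL)
      so <- config$spacing_offset
      if (identical(so, "uniform")) {
        # uniform placement of the MAZ center within the +/-250 bp window
        stats::runif(1, -half_win + Km, half_win - Km)
      } else if (length(so) == 2) {
        stats::runif(1, so[1], so[2])
      } else as.numeric(so)
    }
    placed <- 0L
    tries <- 0L
    while (placed < config$n_spacing_sites) {
      tries <- tries + 1L
      if (tries > 100L * config$n_spacing_sites)
        stopf("could not place %d spacing sites", config$n_spacing_sites)
      center <- stats::runif(1, 500, L - 500)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      if (plant_site(center, strand, sprintf("site_%03d", placed + 1L),
                     spacing_maz)) {
        placed <- placed + 1L
      }
    }
  }
  # apply every collected placement in one pass
  if (length(env$starts)) {
    idx <- unlist(mapply(function(s, w) (s + 1L):(s + nchar(w)),
                         env$starts, env$words, SIMPLIFY = FALSE))
    codes[idx] <- utf8ToInt(paste(env$words, collapse = ""))
  }
  genome <- stats::setNames(intToUtf8(codes), config$chrom)
  motifs <- env$motifs
  motifs <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(factor = character(), chrom = character(),
               start = integer(), strand = character(), site = character())
  rownames(motifs) <- NULL
  list(genome = genome, motifs = motifs)
}

#' Build ChIP-like peaks around planted motif instances
#'
#' One peak of `config$peak_width_bp` centered on each planted instance of
#' the factor, with log-normal signal; optional decoy peaks (carrying no
#' planted motif) at `config$decoy_peak_rate` per true peak.
#'
#' @param config a [scenario_config()].
#' @param motifs truth motif data frame from [make_genome()].
#' @param factor factor name (`"CTCF"` or `"MAZ"`).
#' @return peak data frame (`chrom`, `start`, `end`, `name`, `signal`),
#'   sorted; decoys named `decoy_*`.
#' @export
make_peaks <- function(config, motifs, factor) {
  m <- motifs[motifs$factor == factor, , drop = FALSE]
  K <- nchar(pwm_consensus(if (factor == "CTCF") config$ctcf_pwm else
    config$maz_pwm))
  stopifnot(config$peak_width_bp >= K)
  half <- config$peak_width_bp %/% 2
  mid <- m$start + K / 2
  start <- pmax(0L, as.integer(round(mid - half)))
  peaks <- data.frame(chrom = m$chrom, start = start,
                      end = start + config$peak_width_bp,
                      name = sprintf("%s_peak_%d", factor, seq_len(nrow(m))),
                      signal = stats::rlnorm(nrow(m),
                                             log(config$peak_signal_mean),
                                             0.5),
                      stringsAsFactors = FALSE)
  n_decoy <- as.integer(round(config$decoy_peak_rate * nrow(m)))
  if (n_decoy > 0) {
    ds <- as.integer(stats::runif(n_decoy, 0,
                                  config$chrom_size - config$peak_width_bp))
    peaks <- rbind(peaks,
                   data.frame(chrom = config$chrom, start = ds,
                              end = ds + config$peak_width_bp,
                              name = sprintf("decoy_%d", seq_len(n_decoy)),
                              signal = stats::rlnorm(n_decoy,
                                                     log(config$peak_signal_mean),
                                                     0.5),
                              stringsAsFactors = FALSE))
  }
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

# expected contact matrix (dense) for one condition
expectation_matrix <- function(config, loops, tad_boundaries,
                               loop_factors) {
  bs <- config$bin_size
  n <- floor(config$chrom_size / bs)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- (d + 1)^(-config$alpha)
  if (length(tad_boundaries)) {
    edges <- c(0L, tad_boundaries, n)
    for (t in seq_len(length(edges) - 1L)) {
      lo <- edges[t] + 1L
      hi <- edges[t + 1L]
      E[lo:hi, lo:hi] <- E[lo:hi, lo:hi] * config$tad_enrichment
    }
  }
  if (!is.null(loops) && nrow(loops)) {
    for (i in seq_len(nrow(loops))) {
      bi <- loops$start5[i] %/% bs + 1L
      bj <- loops$start3[i] %/% bs + 1L
      f <- loop_factors[i]
      halo <- 1 + (f - 1) / 2
      for (di in -1:1) for (dj in -1:1) {
        a <- bi + di; b <- bj + dj
        if (a < 1 || b < 1 || a > n || b > n) next
        mult <- if (di == 0 && dj == 0) f else halo
        E[a, b] <- E[a, b] * mult
        E[b, a] <- E[a, b]
      }
    }
  }
  # scale so the expected total count over the upper triangle = depth
  tot <- sum(E[upper.tri(E, diag = TRUE)])
  E * (config$depth / tot)
}

#' Poisson-sample contact maps for WT and KO conditions
#'
#' The expected pixel is depth-scaled `(|i - j| + 1)^(-alpha)`, multiplied
#' by the TAD factor when both bins fall in one planted TAD and by the
#' loop factor at each planted loop's anchor pixel (1-bin halo at half
#' strength). Counts are Poisson-sampled per replicate. In the KO
#' condition, every loop-associated pixel factor of the attenuated loop
#' subset is multiplied by `ko_attenuation`, so the KO/WT expected ratio
#' at those pixels equals the attenuation.
#'
#' @param config a [scenario_config()].
#' @param loops loop data frame from [make_loops()] (or `NULL`).
#' @param tad_boundaries 0-based boundary bin indices.
#' @return list with `wt` and `ko` (lists of [contact_matrix()], one per
#'   replicate), `perturbed` (logical per loop: attenuated in KO), and
#'   `expected_wt` / `expected_ko` matrices.
#' @export
make_contact_maps <- function(config, loops = NULL,
                              tad_boundaries = integer(0)) {
  n_loops <- if (is.null(loops)) 0L else nrow(loops)
  wt_factors <- rep(config$loop_enrichment, n_loops)
  perturbed <- rep(FALSE, n_loops)
  if (n_loops > 0 && config$ko_fraction > 0) {
    n_pert <- as.integer(round(config$ko_fraction * n_loops))
    perturbed[sample.int(n_loops, n_pert)] <- TRUE
  }
  E_wt <- expectation_matrix(config, loops, tad_boundaries, wt_factors)
  # KO: every loop-associated pixel (center + halo) of the attenuated
  # subset is multiplied by the attenuation factor, so the KO/WT expected
  # ratio at those pixels is exactly ko_attenuation; the slightly smaller
  # KO total emulates the lost loop contacts and is handled downstream by
  # CPM normalization
  E_ko <- E_wt
  if (n_loops > 0 && any(perturbed)) {
    bs <- config$bin_size
    nb <- floor(config$chrom_size / bs)
    for (i in which(perturbed)) {
      bi <- loops$start5[i] %/% bs + 1L
      bj <- loops$start3[i] %/% bs + 1L
      for (di in -1:1) for (dj in -1:1) {
        a <- bi + di; b <- bj + dj
        if (a < 1 || b < 1 || a > nb || b > nb) next
        E_ko[a, b] <- E_wt[a, b] * config$ko_attenuation
        E_ko[b, a] <- E_ko[a, b]
      }
    }
  }
  draw <- function(E) {
    n <- nrow(E)
    ut <- upper.tri(E, diag = TRUE)
    x <- stats::rpois(sum(ut), E[ut])
    M <- matrix(0, n, n)
    M[ut] <- x
    M <- M + t(M) - diag(diag(M))
    contact_matrix(config$chrom, config$bin_size, M)
  }
  wt <- lapply(seq_len(config$n_replicates), function(r) draw(E_wt))
  ko <- lapply(seq_len(config$n_replicates), function(r) draw(E_ko))
  list(wt = wt, ko = ko, perturbed = perturbed,
       expected_wt = E_wt, expected_ko = E_ko)
}

#' Simulate a full scenario with ground truth
#'
#' Seeds the scenario stream once and draws, in a fixed documented order:
#' loops, TAD boundaries, the genome with planted motifs, peaks, and
#' (optionally) contact maps. Fixed seed implies a bit-identical scenario.
#'
#' @param config a [scenario_config()] or preset name for
#'   [scenario_preset()].
#' @param seed optional override of `config$seed`.
#' @param contact_maps generate Poisson contact maps (default `TRUE`;
#'   motif/orientation-only studies can skip them).
#' @return object of class `scenario`: list with `config`, `genome`,
#'   `loops`, `truth` (list: `motifs`, `classes`, `tad_boundaries`,
#'   `perturbed`), `peaks` (per factor), and `maps` (or `NULL`).
#' @export
simulate_scenario <- function(config, seed = NULL, contact_maps = TRUE) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  lp <- make_loops(config)
  tad_boundaries <- draw_tad_boundaries(config)
  gm <- make_genome(config, lp$loops, lp$classes)
  peaks <- list(CTCF = make_peaks(config, gm$motifs, "CTCF"),
                MAZ = make_peaks(config, gm$motifs, "MAZ"))
  maps <- NULL
  perturbed <- logical(0)
  if (contact_maps) {
    maps <- make_contact_maps(config, lp$loops, tad_boundaries)
    perturbed <- maps$perturbed
  }
  structure(list(config = config, genome = gm$genome, loops = lp$loops,
                 truth = list(motifs = gm$motifs, classes = lp$classes,
                              tad_boundaries = tad_boundaries,
                              perturbed = perturbed),
                 peaks = peaks, maps = maps),
            class = "scenario")
}

#' Write a scenario to disk in exchange formats
#'
#' Emits FASTA genome, per-factor peak BEDs, loop BEDPE, MEME motifs, COO
#' contact matrices per condition/replicate and a JSON truth table.
#'
#' @param scn a `scenario` from [simulate_scenario()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(scn$genome, file.path(dir, "genome.fa"))
  write_bed(scn$peaks$CTCF, file.path(dir, "peaks_CTCF.bed"))
  write_bed(scn$peaks$MAZ, file.path(dir, "peaks_MAZ.bed"))
  write_bedpe(scn$loops, file.path(dir, "loops.bedpe"))
  write_meme_motif(scn$config$ctcf_pwm, file.path(dir, "motif_CTCF.meme"))
  write_meme_motif(scn$config$maz_pwm, file.path(dir, "motif_MAZ.meme"))
  if (!is.null(scn$maps)) {
    for (r in seq_along(scn$maps$wt)) {
      write_matrix_coo(scn$maps$wt[[r]],
                       file.path(dir, sprintf("matrix_wt_rep%d.coo", r)))
      write_matrix_coo(scn$maps$ko[[r]],
                       file.path(dir, sprintf("matrix_ko_rep%d.coo", r)))
    }
  }
  truth <- list(seed = scn$config$seed,
                classes = as.list(stats::setNames(scn$truth$classes,
                                                  scn$loops$name)),
                tad_boundaries = scn$truth$tad_boundaries,
                perturbed = if (length(scn$truth$perturbed))
                  scn$loops$name[scn$truth$perturbed] else character(0),
                motifs = scn$truth$motifs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
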