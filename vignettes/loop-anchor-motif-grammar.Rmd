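---
title: "Methods: motif grammar at loop anchors and contact-matrix analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif grammar at loop anchors and contact-matrix analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, conventions
and numerical choices. Everything quantitative claimed here is computed
by the test suite or by `scripts/acceptance.R`; nothing is quoted from
external data.

## Coordinates and containers

All coordinates are 0-based half-open on the forward strand — BED and
BEDPE native — so conversion happens only at I/O. A loop's 5ʹ anchor is
defined as the lower-coordinate anchor: genomic order is the only
reproducible definition when loop files arrive with anchors in arbitrary
order. Inter-chromosomal loop records are skipped with a warning because
every analysis in the package is cis. Contact matrices are plain dense
symmetric matrices per chromosome with a declared bin size; the text
exchange format is COO triplets under a `# chrom bin_size n_bins`
header, with duplicate records summed and every record mirrored.

## PWM scanning and exact p-values

A motif is a position probability matrix over A,C,G,T with a background
distribution. A word of the motif's length scores
\(S = \sum_k \log_2 (p_k(b_k)/q(b_k))\) bits; the `-` strand scores the
reverse complement. The p-value of a score is the exact survival
probability of the discretized score of a random background word,
obtained by convolving per-position score distributions (dynamic
programming). Choices that matter:

* **Granularity.** The score lattice step defaults to `1e-3` bits,
  automatically coarsened so the lattice stays within \(10^5\) cells —
  exactness versus memory. For the PWMs used here the lattice is well
  below that cap. The scanner computes each window's *integer* lattice
  score with the same per-position table used by the DP, so lookup and
  null are always consistent, on both strands.
* **Ambiguity codes.** Windows containing `N` are skipped and counted in
  a message; no hit is emitted. Background models beyond 0-order are out
  of scope.
* **Overlaps.** All hits above threshold are reported; selection of a
  single hit happens only at anchor annotation. Score ties there break
  to the lowest start, then the `+` strand — the classification needs a
  deterministic single hit and "highest score" alone does not provide
  one.
* The scan p-value cutoff defaults to `1e-3`, the conventional
  threshold for associating anchors with motifs.

For motif lengths up to 6 the DP null is verified against full \(4^K\)
enumeration to \(10^{-12}\); the sliding scan is verified against a
naive per-word rescoring oracle on random sequences.

## Anchor annotation and the orientation grammar

Per factor, the motif search region of an anchor is the union of its
intersections with that factor's ChIP peaks — occupancy plus sequence is
a far stronger signal than sequence alone, and restricting the search
suppresses false positives. When an anchor overlaps several peaks, the
union of intersections is searched: that is the least lossy reading of
"anchor ∩ peaks". Hits inside the anchor but outside every peak are
never assigned.

With \(s_5, s_3\) the strands of the best hits at the two anchors:
\((+,-)\) is convergent, \((-,+)\) divergent, equal strands tandem, and
a missing hit leaves the loop unclassified. Proportions are reported
over classified loops only — the three orientation groups form the
denominator — because a loop with no motif pair carries no orientation
information; unclassified counts are still reported alongside.

The cofactor-placement call (`relative_orientation`) defaults to the
positional reading: on the 5ʹ anchor, "inside" means the cofactor motif
midpoint lies at a greater coordinate than the primary's; mirrored on
the 3ʹ anchor; ties are "outside". Whether "towards the inside of the
loop" denotes position or motif strand is genuinely ambiguous, so a
strand-based variant (`mode = "strand"`: cofactor strand pointing
loop-ward) is exposed without asserting which reading is canonical.

## Motif spacing

For each deduplicated primary hit (overlapping primaries keep the
highest score), a 500-bp window centered on the primary midpoint is
scanned with the secondary PWM; the best hit's center-to-center distance
is recorded, signed by the primary's orientation (positive = downstream
of the primary's `+` direction — the convention of spacing tools this
analysis follows). Distances are histogrammed at 5-bp bins — fine enough
to localize a 70–140-bp preferred offset, coarse enough to keep per-bin
counts stable — and each bin gets a one-sided binomial test against the
uniform-placement null \(p_0 = \text{bin width}/\text{window}\),
BH-corrected across bins. Windows that would leave the chromosome are
skipped and counted. The uniform null is marginally conservative at the
window edges (a motif center cannot fall within half a motif length of
the edge), which the null-calibration test bounds empirically.

## Contact-matrix methods

* **Binning.** Read pairs closer than 25 kb are discarded (self-ligation
  range), the rest tallied into 20-kb bins by default.
* **ICE balancing.** All-zero bins plus the lowest-coverage 2% of
  nonzero bins are masked; per-bin biases are updated iteratively until
  unmasked row sums agree to a relative `1e-6` (at most 500 iterations;
  non-convergence is an error carrying the last deviation). The balanced
  layer is rescaled to the unmasked raw total so counts stay
  interpretable. Balancing is idempotent and agrees with an alternating
  row/column (Sinkhorn) oracle up to row-normalization.
* **Expected-by-distance.** Mean over unmasked pixels per bin distance;
  an optional monotone smoothing (running minimum) for sparse far
  diagonals, off by default.
* **APA.** For each loop whose pixel (pair of anchor-midpoint bins) is
  at least \(2N+2\) bins from the diagonal and \(N\) bins from the matrix
  edge, the \((2N+1)^2\) observed/expected window is averaged; \(N = 10\)
  flank bins at 5-kb resolution by default. A bin-size mismatch with
  the requested resolution is an error — no silent re-binning. P2LL is
  the central pixel over the mean of a corner block of
  \(\lfloor(2N+1)/3\rfloor\) bins; with rows indexed by upstream-anchor
  offset the default corner is the lowest row/column indices, and the
  corner choice is configurable because it depends on display
  orientation. On O/E input a P2LL of 1 means no loop signal. A raw-sum
  aggregation mode is available behind a flag.
* **Boundary score.** For bin \(i\) and window \(W\) bins, the mean of
  cross pixels \(\{(a,b): i-W \le a < i < b \le i+W\}\) over the mean of
  the two flanking intra-window triangles. The ratio is oriented
  cross/intra so that boundaries — which insulate — have *low* scores.
  Scores are undefined (masked) where the window is incomplete near
  chromosome ends. Boundaries are exact-tie-aware local minima with
  z-score at most \(-1\) against the track mean/SD (a flat track has no
  boundaries); TADs are the intervals between consecutive boundaries.
  The TAD-calling window defaults to 500 kb; 250-kb and 1-Mb windows are
  supported for multi-scale scoring.
* **Intra-TAD activity.** The mean observed/expected over intra-TAD
  pixels. The upstream definition of this magnitude lives in a tool
  chain not re-implemented here; mean O/E is used as the package's
  definition and documented as such — every comparison made with it is
  relative, which is all the downstream tests require. TADs under 3
  bins are flagged as unstable.
* **Differential activity.** Counts (for loops: raw counts summed over
  the 3×3 pixel window centered on the loop pixel; the window lifts
  counting noise without blurring neighboring loops) are CPM-normalized
  by the replicate's total read pairs. log2 fold change compares mean
  CPMs with a +0.5 prior; the p-value is the exact conditional Poisson
  rate test (binomial on pooled counts with the library-size split as
  null proportion), BH-corrected. Loop significance uses FDR ≤ 0.005
  and |log2FC| ≥ 1.5; TAD-style testing uses FDR ≤ 0.05 with no
  fold-change cutoff. Swapping condition labels negates every log2FC
  and preserves p-values exactly.
* **Simple loop caller.** A deliberately minimal Poisson caller (pixel
  p-values against the distance expectation, BH, 8-connected cluster
  maxima) included so synthetic pipelines run end-to-end; it stands in
  for spline-refined production callers and is labeled accordingly.

## The synthetic generator

`simulate_scenario` seeds one RNG stream and draws, in a fixed order:
loops → TAD boundaries → genome → motif placements → peaks → contact
maps. A fixed seed therefore reproduces the entire scenario
bit-identically; tests assert distributional truths, not cross-platform
byte equality of the RNG.

Defaults are chosen to emulate the statistical regime the analyses
assume, and they are the conditions under which the acceptance tests
run (not dials to be tuned per test):

* chromosome of 40 Mb, 20-kb bins; 300 loops with class mixture
  (0.60, 0.30, 0.10) for convergent/tandem/divergent;
* anchor distances lognormal(meanlog = log(600 kb), sdlog = 0.9),
  truncated below at 100 kb — about 90% of loops under 2 Mb, matching
  the observation that most loops span less than that;
* a sharp synthetic 19-bp CTCF-like PWM and the 7-bp GGGAGGG MAZ-like
  PWM (consensus planted at 0.97 per-position probability); any real PWM
  can be supplied instead — the analyses never hard-code a motif;
* MAZ planted 70–140 bp from CTCF (uniform), co-oriented, on the side
  given by the CTCF strand;
* ChIP-like peaks of 200 bp centered on planted instances with
  log-normal signal; optional motif-free decoy peaks;
* contact expectation \((d+1)^{-\alpha}\) with \(\alpha = 1\), TAD
  blocks of 0.4–1.2 Mb at 2.5× intra enrichment, loop pixels at 3×
  with a 1-bin halo at half strength, Poisson-sampled at \(10^6\) pairs
  per replicate, two replicates per condition;
* the knockout condition multiplies every loop-associated pixel (center
  and halo) of a random 30% of loops by 0.25, so the KO/WT expected
  ratio at perturbed pixels is exactly the attenuation factor.

What the generator does **not** emulate: read-level artifacts
(ligation junctions, mappability), fragment-resolution Hi-C structure,
compartment checkerboards, non-uniform background sequence composition
(CpG islands, repeats), or correlated replicate noise. Passing the
planted-truth tests therefore demonstrates the correctness of the
computations under the stated statistical model, not performance on any
particular organism's data.

## Problem sizes used by the validation suite

The acceptance checks run on: 50 random 2-kb sequences × 3 PWMs for the
scanning oracle; full \(4^K\) enumeration at \(K = 4..6\); the 300-loop
default scenario for orientation recovery; 500 spacing sites (70% at
+85 bp) plus twenty 250-site uniform-placement runs for null
calibration; 500×500 random matrices for ICE; a 10-Mb, 5-kb-bin map
with 200 loops at 3× for APA (and a loop-free map scored at a random
loop list as the null); a 10-Mb, 20-kb-bin map with 2.5× TADs for
boundary recovery; a 20-Mb map with 150 loops, 30% attenuated 4-fold,
for differential testing; and the full default pipeline run twice for
byte-identical determinism. These sizes were picked so the whole suite
completes in minutes on one core while leaving each statistical check
comfortably powered.

## Known limitations

* Dense matrices cap practical chromosome sizes at a few thousand bins;
  genome-wide runs should iterate per chromosome.
* The exact binomial/Poisson differential test ignores biological
  overdispersion across replicates; with many replicates a
  negative-binomial framework would be preferable.
* The boundary z-cutoff (default 1) is a display-scale heuristic;
  multi-scale consensus calling across the three window sizes is left
  to the user.
* Motif p-values assume a 0-order background; GC-rich motifs like
  GGGAGGG will hit more often in GC-rich isochores than the global null
  suggests.
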