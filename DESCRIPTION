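Package: loopgrammar
Title: Motif Grammar at Chromatin Loop Anchors and Contact-Matrix Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the transcription-factor motif grammar of
    chromatin loops called from Hi-C data. Scans loop-anchor sequences with
    position weight matrices using exact dynamic-programming p-values,
    classifies loops as convergent, divergent or tandem from the strands of
    the best anchor motifs, and measures the spacing between a primary motif
    (such as CTCF) and a nearby cofactor motif (such as the MAZ GGGAGGG
    element). Also provides binned contact-matrix utilities: iterative
    correction (ICE) balancing, distance-decay expected profiles, aggregate
    peak analysis with the peak-to-lower-left (P2LL) statistic,
    insulation-style boundary scores and TAD calls, intra-TAD activity, and
    differential loop/TAD activity testing with CPM normalization. A fully
    deterministic synthetic-data generator plants motifs, loops, TADs and
    Poisson-sampled contact maps with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
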