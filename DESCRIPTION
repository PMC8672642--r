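Package: svforge
Title: Structural Variant and Long-Read Simulation, Benchmarking and
    Multi-Caller Consensus
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating long-read structural-variant (SV)
    detection pipelines. Simulates diploid genomes carrying deletions,
    insertions, duplications, inverted duplications, inversions,
    translocations and complex substitutions; simulates long sequencing
    reads with trainable 3-mer context-specific error profiles and
    depth-profile-driven coverage; scores caller VCFs against a truth
    set with position/length tolerances and a weighted per-call score;
    and merges the output of multiple SV callers into a consensus call
    set using support thresholds, per-statistic caller priorities and
    single-caller rescue rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
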