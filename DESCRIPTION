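Package: mitorecomb
Title: Repeat-Mediated Recombination Analysis for Multipartite Organelle Genomes
Version: 0.1.0
Authors@R: person("Mitorecomb", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects pairs of repeated sequences in circular (multipartite)
    plant mitochondrial genomes, builds flank-swap conformation references for
    each repeat pair, counts long reads spanning each conformation to estimate
    recombination frequencies, predicts the molecular products of a single
    homologous-recombination event (circle fission, fusion and segment
    inversion), and scans for mitochondrial plastid transfers (MTPTs) by local
    similarity search against a chloroplast genome. A seeded synthetic-data
    generator produces genomes with planted repeats and plastid-derived
    segments, conformer molecule pools at stated mixture fractions, and
    error-bearing nanopore-like long reads with truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
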