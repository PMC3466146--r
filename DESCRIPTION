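Package: tssr
Title: Translation Stop Signal Ratio Profiling of Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Alignment-free phylogenetic profiling of bacteria from the
    translation stop signals (TAA, TAG, TGA) found on all three reading
    frames of protein-coding genes.  Counts in-frame stop codons and
    off-frame (premature/hidden) stop-like trimers per gene, computes
    Genic and Genomic translation stop signal ratios (TSSR), clusters
    genome profiles with city-block distance and complete linkage,
    performs correspondence analysis of per-gene signal counts with group
    centroids and confidence ellipses, and tests positional (replichore,
    strand, origin/terminus) bias of gene profiles with a
    permutation-calibrated Kolmogorov-Smirnov statistic.  Includes a
    codon-usage based gene simulator with an exact expected-count oracle
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
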