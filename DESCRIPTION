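Package: nucdyn
Title: Nucleosome Dynamics from Multi-Condition MNase-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end analysis of nucleosome positioning dynamics from
    MNase-seq fragment data across growth conditions: per-bp nucleosome
    occupancy tracks (fragment-midpoint pileup with Gaussian smoothing),
    nucleosome calling with +1/-1 assignment and nucleosome-free region
    (NFR) delineation per gene, TATA-stratified metagene profiles around
    transcription start sites and stop codons, differential NFR occupancy
    between conditions (ratio, 2x2 chi-square, Benjamini-Hochberg q-values,
    fold + q filtering, decile occupancy classes, correlation and Wilcoxon
    comparisons), and concordance of nucleosome-based calls with qRT-PCR
    2^-ddCt expression fold changes. Includes a seeded synthetic MNase-seq
    generator with ground truth (phased arrays, NFRs, TATA-dependent +1
    occupancy, condition-dependent NFR effects) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    ggplot2,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
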