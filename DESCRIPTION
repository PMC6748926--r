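Package: sodamat
Title: Core Microbiome, Selection and Proteome Allocation Analyses for
    Soda Lake Microbial Mats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analyses for multi-lake microbial mat surveys of
    alkaline soda lakes: detection of a core microbiome from OTU count
    tables across lakes and years, relative sequence abundance of
    metagenome-assembled genomes (MAGs) from per-contig coverage, a
    codon-aware diversifying-selection screen on aligned core-gene
    variants, fragment-based average nucleotide identity with a
    distance-abundance correlation between lake regions, and
    NSAF-style metaproteome resource-allocation accounting. Every input
    kind can be simulated with planted ground truth, so the whole
    pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
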