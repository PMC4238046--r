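Package: transwitch
Title: Translatome-Switch Analysis for Polysome Profiling Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying translationally regulated genes from paired
    translatome (polysome-bound) and transcriptome expression studies. Implements
    Z-ratio differential expression with detection filtering, permutation-based
    empirical false discovery rates and variance exclusion; translatome-exclusive
    gene calling with Venn partitions; window-constrained hypergeometric 5'-UTR
    motif over-representation with bias diagnostics and position-weight-matrix
    comparison; spike-in-normalized quantification of transcript distribution
    across sucrose-gradient fractions; and first-order decay fitting for protein
    and mRNA stability time courses. Ships seeded synthetic-data generators with
    planted ground truth so every stage can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
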