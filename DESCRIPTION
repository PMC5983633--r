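Package: mirstalk
Title: Small RNA-Seq miRNA Discovery, Differential Expression and Degradome
    Cleavage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, re-runnable pipeline for plant small-RNA
    sequencing studies: read filtering and adapter trimming, collapsing to
    unique tags, exact (zero-mismatch) genome mapping, annotation of known
    miRNAs against mature/hairpin reference sets, novel miRNA discovery with
    hairpin folding and stability metrics (MFE, MFEI), TPM normalisation and
    negative-binomial differential expression with a |log2FC| >= 1 and
    adjusted p <= 0.05 decision rule, complementarity-penalty target
    prediction, and degradome (PARE) cleavage-site profiling with the
    five-category classification. A seeded synthetic-data generator emits toy
    genomes with planted hairpins, sRNA libraries over a tissue x treatment x
    replicate design, and degradome reads with planted cleavage peaks,
    together with a ground-truth manifest for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
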