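Package: clonescribe
Title: Clonal Barcode Tracing and stgRNA Expression-Recording Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for lentiviral DNA-barcode clonal tracing
    combined with Cas9 self-targeting gRNA (stgRNA) gene-expression
    recording. Provides a synthetic-data generator for barcoded tumor
    clonal dynamics (growth, bottlenecks, selection, expression-coupled
    stgRNA editing), FASTQ read filtering and barcode/stgRNA extraction,
    Hamming-distance barcode error collapsing, clonal diversity statistics
    (Shannon entropy, effective barcode numbers, Jensen-Shannon divergence),
    a minimum-mutation-score affine-gap aligner with wrong-template
    blacklist filtering, and weighted Spearman association between recorded
    expression and clonal abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    vegan
Config/testthat/edition: 3
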