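Package: cnvpost
Title: Post-Processing, Ensemble Merging and Random-Forest Filtering of
    Copy Number Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts the heterogeneous VCF output of short-read structural
    variant callers (Delly, GRIDSS, LUMPY, Manta) into novel adjacencies,
    reclassifies them into four copy-number-variant types (deletion,
    insertion, tandem duplication, dispersed duplication) -- recovering
    dispersed duplications that callers mis-report as overlapping deletion
    plus tandem-duplication pairs -- merges concordant calls across callers,
    and filters the merged set with a random-forest classifier trained with
    cross-validated grid search. Includes optional read-depth and
    flanking-gap filters, and a spike-in simulator and evaluator so the whole
    pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
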