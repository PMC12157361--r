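Package: ecdnatools
Title: Purity-Aware ecDNA Detection, Genome Instability Metrics, and
    Association Statistics for Lung Cancer Whole Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of the bespoke computational stages of
    a large lung-cancer extrachromosomal DNA (ecDNA) whole-genome study:
    purity/ploidy-corrected total copy number rescaling and amplicon seed
    calling, a simplified breakpoint-graph amplicon classifier (ecDNA, BFB,
    complex non-cyclic, linear), genome-instability metrics (whole-genome
    doubling, wGII, telomere tumor/normal ratio, mitochondrial copy number),
    high-confidence chromothripsis criteria, ecDNA cargo and driver-mutation
    classification, and an association/survival statistics layer (logistic
    and Firth-penalized logistic regression, BH-FDR, Mann-Whitney, exact 2x2
    tests, Cox proportional hazards). A synthetic-cohort generator with known
    ground truth exercises the whole pipeline offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    IRanges,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
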