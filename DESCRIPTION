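Package: promdiver
Title: Alternative Promoter Repertoire and Gene-Level Trait Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a gene's alternative-promoter (AP) repertoire, derived by
    gap-based clustering of transcription start site (TSS) evidence, to its
    differential-expression frequency across expression datasets, its
    membership in disease and cancer-driver gene sets, its gene-structure
    lengths, its duplicability, and its degree in a protein-interaction
    network.  Provides readers for BED6 TSS evidence, tri-state
    differential-expression call matrices, BED12 gene models, plain gene
    lists and interaction edge lists; a per-gene differential expression
    ratio (DER) statistic with a measured-fraction filter; an exact
    statistical core (Fisher 2x2 exact test, Wilcoxon rank-sum test); a
    fixed four-rung promoter-class comparison ladder; and a seeded synthetic
    cohort generator with planted class effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    rtracklayer,
    BiocGenerics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
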