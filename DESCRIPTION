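Package: holoshare
Title: Multi-Site Host Microbiota Analysis with Negative-Control
    Decontamination and Within-Animal Taxon Sharing Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amplicon sequence variant (ASV) tables
    collected from several body sites of the same animals over time, as in
    longitudinal dairy-herd microbiota studies. Provides abundance and
    prevalence filtering, negative-control ("kitome") decontamination,
    rarefaction, alpha diversity, Jaccard, Bray-Curtis and (weighted)
    UniFrac dissimilarities with principal coordinates ordination,
    permutation-based PERMANOVA and beta-dispersion tests, Ward clustering
    with Adjusted Rand Index stability, core-microbiota computation, and
    within-animal cross-site ASV sharing statistics. A synthetic herd
    generator with planted contaminants, core taxa and transfer structure
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    biomformat,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
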