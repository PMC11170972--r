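Package: panlachno
Title: Comparative Genomics of Gut Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of the comparative-genomics
    workflow used to characterize large cultivated genome collections of gut
    bacteria (exemplified by the family Lachnospiraceae): fragment-mapping
    average nucleotide identity (ANI) with complete-linkage species delineation
    at 95% ANI, 16S rRNA novelty gating at the 98.7%/94.5% species/genus
    thresholds with greedy OTU clustering, greedy incremental gene-family
    clustering with core/soft-core/shell/cloud partitioning and accumulation
    curves, short-chain fatty acid pathway-completeness scoring from protein
    homology, sporulation signature screening with principal coordinates
    analysis, reference-anchored SNP calling with impact classes and
    neighbor-joining trees, and negative-binomial differential-abundance
    marker detection with Benjamini-Hochberg control and co-occurrence
    networks. A seeded synthetic genome-collection generator with planted
    ground truth makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    ape,
    vegan,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
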