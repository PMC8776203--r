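Package: tctargets
Title: Time-Resolved Classification of Treatment-Responsive Genes in Two-Arm RNA-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a two-arm (treated versus solvent control), multi-time-point
    bulk RNA-seq count experiment into a classified catalogue of responder
    genes. Provides a negative-binomial simulator with planted trajectory
    archetypes as a recovery oracle, TMM/CPM preprocessing, a fold-change
    threshold (TREAT-style) Wald test per time point with Cox-Reid dispersion
    estimation, timing/direction/profile classification of target genes,
    k-means clustering of standardized expression trajectories with automatic
    direct/indirect labelling, gene-set over-representation with direction
    calls, and peak-gene colocalization within TAD-scale windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
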