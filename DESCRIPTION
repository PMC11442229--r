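Package: cranmetaqtl
Title: Meta-QTL Co-Location Analysis for Outbred Cranberry Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An analysis pipeline for mapping berry quality and yield traits in
    four-way outbred cranberry crosses and condensing the resulting QTL into
    consensus meta-QTL. Includes a synthetic-data generator for four-way-cross
    genotypes and multi-year, spatially structured phenotypes with known ground
    truth; conversion of categorical berry-shape scores into per-genotype
    "chimera" silhouettes via differential distance transforms, with chain-code
    and moment-based shape descriptors; REML estimation of genomic variance
    components, BLUPs and narrow-sense genomic heritability; Haley-Knott
    genome scans with permutation thresholds, 1.5-LOD support intervals and
    four-way parental effect contrasts; and a meta-QTL engine that represents
    QTL support-interval overlap as an undirected graph and synthesizes each
    maximal clique into a consensus region with intersected extents and
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    splines,
    EBImage,
    igraph,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
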