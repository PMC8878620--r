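Package: cymbodiv
Title: Marker and Phytochemical Diversity Analysis of Citronella Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dominant (presence/absence) SSR marker diversity
    analysis of germplasm collections, built around the Java citronella
    (Cymbopogon winterianus) core collection: per-primer informativeness
    statistics (PIC, EMR, MI, band informativeness and resolving power),
    POPGENE-style population diversity and differentiation (na, ne, h,
    Shannon I, Ht, Hs, Gst, Nm), Nei genetic identity/distance with a UPGMA
    dendrogram, Jaccard similarity with neighbour-joining and principal
    coordinate analysis, distance-based AMOVA with a permutation test of
    PhiPT, and Euclidean complete-linkage chemotype clustering of essential
    oil composition. Includes a Balding-Nichols band-matrix simulator with
    controllable population divergence for validating every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
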