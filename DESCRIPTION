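Package: dendrobarcode
Title: Molecular Authentication of Dendrobium Species from rDNA ITS Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-reproducible pipeline for DNA-barcode authentication of
    Dendrobium species from the nuclear ribosomal ITS region (ITS1-5.8S-ITS2).
    Partitions amplicons into ITS1/5.8S/ITS2 by anchoring a conserved 5.8S
    reference, computes per-region length and GC statistics, aligns sequences
    (affine-gap pairwise and progressive multiple alignment), estimates Kimura
    2-parameter distances with pairwise or complete deletion, builds
    neighbor-joining and maximum-parsimony trees with nonparametric bootstrap
    support, extracts angle/length/loop features from four-helix ITS2 secondary
    structures, and clusters the feature vectors by Manhattan distance with
    average linkage. A synthetic-data generator emulates the statistical
    structure of section-level ITS variation so every stage is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
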