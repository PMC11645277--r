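Package: vascmap
Title: Combinatorial smFISH Decoding and Binned Vascular Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for 100-plex combinatorial single-molecule
    FISH (Molecular Cartography style) data: per-plane spot detection with
    z-linking, iterative feature filtering to a volume-based target, rigid
    iterative-closest-point registration of imaging rounds with tri-linear
    stack resampling, per-pixel 16-value profile decoding against a binary
    codebook with specificity estimation from unused codes, square-tile
    transcript binning, marker-based vessel segmentation with caliber
    classification, and rank-sum/Benjamini-Hochberg group statistics. Includes
    a synthetic-data generator (codebooks, vessel scenes, rendered multi-round
    stacks, low-plex RNAscope-style fixtures) so every stage is testable
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
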