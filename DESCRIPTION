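Package: nanomapr
Title: Two-Color Nanochannel Genome-Map Construction and Assembly Validation
Version: 0.1.0
Authors@R: person("nanomapr", "developers", role = c("aut", "cre"),
    email = "nanomapr@example.org")
Description: Builds consensus sequence-motif maps from noisy single-molecule
    nick-label data imaged in nanochannel arrays, tiles per-clone consensus
    maps into a region genome map, and uses that map to validate and correct
    draft sequence assemblies. Provides in silico two-color digestion of DNA
    sequences with nicking-endonuclease motifs, a single-molecule simulator
    with known ground truth, hierarchical clustering and Gaussian peak
    fitting for consensus construction, a dynamic-programming aligner for
    ordered two-color maps, discrepancy classification (extra sequence,
    missing sequence, interval mismatch, high label density), scaffold
    anchoring into gaps, and text readers/writers for BNX-, CMAP- and
    XMAP-style formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
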