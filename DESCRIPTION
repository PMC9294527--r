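Package: musselid
Title: Barcode-Based Species Identification and Method Agreement for
    Smooth-Shelled Mussels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for DNA-barcode species identification in smooth-shelled
    mussels (Mytilus spp.) from short aligned nuclear markers such as the
    histone H1C fragment.  Implements five identification strategies --
    tree-based placement (FINS), direct sequence comparison (DSC),
    best close match (BCM), all barcodes (AB) and a simplified automatic
    barcode-gap discovery (ABGD) -- together with diagnostic-site discovery,
    IUPAC-ambiguity hybrid detection, pairwise similarity and
    model-corrected distances (p, JC69, K2P, TN93), neighbour-joining trees
    with bootstrap support, and inter-method agreement statistics (Cohen's
    kappa with confidence interval, multiclass Matthews correlation,
    Benjamini-Hochberg correction, Landis-Koch interpretation bands).  A
    seeded synthetic-data generator emulates two closely related species
    pools with fixed diagnostic sites and F1 hybrids so the whole pipeline
    runs reproducibly without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
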