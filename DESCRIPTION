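Package: epsquant
Title: Quantification of Mycelial Biofilm and Bacterial Attachment in SEM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hessian-eigenvalue ridge detection (hard-conditioned Sato filter)
    and morphometry for scanning electron micrographs of fungal-bacterial
    cocultures. Detects thin curvilinear exopolymeric (EPS) biofilm structures,
    segments them from hyphae and rod-shaped bacteria, and computes biofilm
    area and percentage coverage, bacterium length and width, hyphal tube
    width, and the geodesic length of bacterium-hypha attachment structures.
    Includes a synthetic micrograph generator with exact ground truth
    (tube, rod and filament geometry plus per-class masks) so every pipeline
    stage can be validated without access to the original micrographs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    mclust,
    igraph,
    jsonlite,
    png,
    tiff,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
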