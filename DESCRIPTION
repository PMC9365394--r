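Package: kfibergraph
Title: Spatial-Graph Morphometry of Kinetochore-Fibers in 3D Spindle Reconstructions
Version: 0.1.0
Authors@R:
    person("kfibergraph", "developers", email = "kfibergraph@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of microtubule spatial graphs from
    electron-tomography reconstructions of mitotic spindles. Reads
    Amira-style ASCII spatial graphs and a neutral JSON/CSV interchange
    format, and computes kinetochore-microtubule (KMT) counts, length
    distributions, minus-end positioning relative to the spindle poles,
    global and local tortuosity, k-fiber cross-section geometry
    (alpha-shape polygonal areas, KMT enclosure, nearest-neighbour
    spacing), metaphase-plate zoning, and distance-thresholded
    microtubule-microtubule association patterns. A parametric synthetic
    spindle generator with recorded ground truth supports oracle testing
    and parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
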