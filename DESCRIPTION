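Package: atlasquant
Title: Atlas-Based Quantification of Labeled Cells in Brain Section Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Counts immunolabeled cell profiles inside atlas-defined brain
    regions from pixel-aligned 2D section images, corrects profile counts for
    split-cell double counting with Abercrombie's formula, extrapolates to
    whole-region totals via the section sampling interval, and expresses
    results as densities per cubic millimeter of reference-atlas volume.
    Includes region-ontology handling with custom groupings, majority-overlap
    object-to-region assignment, a manual exclusion step for erroneously
    segmented objects, downstream validity/reliability/cross-species/gradient
    analyses, and a synthetic-data generator with exact planted ground truth
    plus a sphere-in-slab sectioning simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
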