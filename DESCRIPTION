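Package: pollenQuant
Title: Automated Pollen Counting and Viability Scoring from Stained Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies pollen number and pollen viability from micrographs of
    Alexander-stained pollen. An image-processing pipeline (background
    subtraction, colour-channel decomposition, auto-thresholding, binary
    morphology, distance-transform watershed, and size/circularity particle
    filtering) yields per-image total pollen counts, viable pollen counts and
    percent viability. A scenario-evaluation layer sweeps named filter
    parameterizations over an image set, correlates automatic counts with
    manual ground-truth counts, and selects the best-performing scenario. A
    seeded synthetic-micrograph generator with exact per-grain ground truth
    supports validation and benchmarking without real micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Visualization
RoxygenNote: 7.3.3
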