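Package: mcsquant
Title: Quantitative Analysis of ER-Plasma Membrane Contact Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying endoplasmic reticulum (ER) to plasma
    membrane (PM) contact-site architecture from electron tomography
    annotations and for scoring genetic interactions from colony plates.
    Reconstructs membrane surfaces from clicked point clouds by plane
    fitting and biharmonic spline interpolation and computes intermembrane
    distance statistics per contact site; derives tilt geometry of bridging
    particles from 4-point picks; extracts subvolumes along membrane paths
    or at particle positions, collapses them to 2D projections, aligns and
    classifies them under orientation-prior constraints, and measures coat
    thickness and rod length from class averages; computes coat-coverage
    ratios from segmentation masks; normalizes synthetic genetic array
    colony sizes and scores log2 interaction ratios; extracts linearized
    cortical fluorescence profiles from 2-channel images. A synthetic-data
    generator produces every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
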