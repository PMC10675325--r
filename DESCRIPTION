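Package: gelscreen
Title: Image-Based Screening of Hydrogel Biodegradation and Therapeutic Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the biodegradation of dye-stained hydrogel discs in a
    millifluidic chip from time-lapse RGB images. Frames are segmented by an
    HSV color gate, stained-gel pixels are grouped by 8-connected component
    labeling, regions are assigned to wells, and per-well disc area is tracked
    over time to yield endpoint degradation pseudorates (percent of initial
    surface area lost per hour) and disintegration-event flags. Released
    compounds in chip eluates are quantified from absorbance readings against
    a linear standard curve, and the visual method is validated against mass
    and eluate measures with Pearson correlation and one-way ANOVA with Tukey
    contrasts. A surface-erosion kinetics simulator and frame renderer supply
    ground-truthed synthetic experiments so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
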