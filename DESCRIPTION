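Package: qwanat
Title: Quantitative Wood Anatomy of Defoliator Outbreak Impacts on Conifer Tree Rings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to derive cell- and ring-level anatomical and functional
    traits from conifer tracheid measurements (lumen diameter, wall thickness,
    lumen and wall areas), including theoretical hydraulic conductivity of
    elliptical conduits, ring wall area as a tree-ring biomass proxy, and
    hydraulic carbon use efficiency. Builds detrended tree-ring chronologies
    with cubic smoothing splines (50 percent frequency cutoff) and Tukey
    biweight robust means, detects insect defoliation outbreaks from
    cell-wall-thickness declines against a non-host control, quantifies
    immediate and legacy outbreak effects with superposed-epoch deviation
    statistics and intra-ring loess profiles, contrasts ring-width and
    anatomy-based biomass-loss estimates, and computes bootstrap correlations
    between chronologies and monthly climate. A seeded synthetic tracheidogram
    generator with ground-truth labels supports calibration and recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
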