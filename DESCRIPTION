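Package: treelineq
Title: Driver Attribution for Alpine Treeline Expansion with the
    Stratified-Heterogeneity q Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to attribute drivers of alpine treeline expansion from
    raster time series. Derives topographic factors (slope, aspect, relief,
    topographic wetness index) from a digital elevation model, downscales
    coarse monthly climate rasters by multiple linear regression on terrain
    covariates, maps binary tree-stand cover with a pluggable classifier,
    turns multi-year presence maps into expansion rates, aspect and slope
    summaries, and a density-increase response surface, and quantifies
    single-factor and interactive factor influence with the
    stratified-heterogeneity q statistic (factor detector and interaction
    detector). A synthetic volcano-landscape generator with known planted
    effects makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
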