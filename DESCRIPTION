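Package: rootbox
Title: Curve Box Plots, Geometric Median Curves and Time-Lines for Root
    Growth Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Visual descriptive statistics for ensembles of growing plant
    roots imaged over several days. Segmented root pixels are reconstructed
    as time-parameterized planar B-spline curves (Dijkstra ordering, de Boor
    knot placement, least-squares fitting), refit into a common spline basis
    and treated as Euclidean coefficient vectors. On these vectors the
    package computes L1 data depth and the geometric median via the modified
    Weiszfeld algorithm, derives curve box-plot zones (interquartile, inlier,
    outlier), fits a thin-plate-spline time field whose isocurves are
    per-day time-lines with confidence zones, and quantifies the stability
    of the median curve with a bootstrap validity indicator. A modified band
    depth baseline, a synthetic root-ensemble generator with known ground
    truth, figure composition (layered SVG and PNG), a compact single-file
    curve store, and the scoring arithmetic of an expert preference survey
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    splines,
    jsonlite,
    igraph,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Visualization, Phenotyping, Spatial, StatisticalMethod
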