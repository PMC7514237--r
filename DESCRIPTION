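Package: intervalpca
Title: Principal Component Analysis for Interval-Valued Data with
    Best-Point Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Principal component analysis for symbolic data whose cells are
    closed intervals rather than single numbers.  Implements the classical
    center method (PCA on interval midpoints with hyper-rectangle vertices
    projected as supplementary elements) and the vertex method (PCA on the
    stacked hyper-rectangle corners), together with the "Best Point" methods
    that search the interval box for the realization matrix that either
    minimizes the squared distance from the vertices to the principal
    subspace or maximizes the variance retained by the leading components.
    Interval component scores are obtained by fast sign-split closed forms
    that provably equal the min/max over all vertex projections, and the
    row-column duality relations yield interval bounds on variable
    coordinates in the correlation circle.  Includes interval-CSV input and
    output, a morphometric faces dataset of facial distances measured over
    image sequences, a synthetic interval-matrix generator, four end-to-end
    comparison pipelines, and principal-plane rectangle plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
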