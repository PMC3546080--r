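Package: sbpquant
Title: Quantification of Corneal Subbasal Nerve Plexus Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated morphometry of pre-segmented corneal subbasal nerve
    plexus (SBP) images from in vivo confocal laser-scanning microscopy.
    Binary nerve masks are analysed in two stages: connected-component
    morphology before skeletonisation, and graph-topological analysis of the
    one-pixel-wide medial axis after skeletonisation. The skeleton is
    converted into a graph of typed nodes (branch points, nerve endings,
    border-crossing connectivity points) and weighted fibre segments, from
    which an eleven-parameter metric set (pixel counts, coverage ratio,
    homogeneity, fibre counts and lengths, fibre density, node counts) is
    assembled and optionally normalised to 1 mm^2. A phantom generator
    produces synthetic fibre networks with exact ground-truth topology and
    analytic lengths for validation, and a statistics module provides
    normality-driven two-group testing (Welch t or Mann-Whitney) and
    stepwise Wilks'-lambda linear discriminant classification of patient
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    igraph,
    MASS,
    nortest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
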