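Package: RangeDynamics
Title: Presence-Background Niche Modelling and Range-Shift Analysis Across
    Climate Periods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing species range dynamics across climate
    periods from presence-only occurrence records. Implements a
    maximum-entropy presence-background suitability model (linear, quadratic
    and hinge features with L1 regularisation and a logistic output),
    distance-constrained spatial thinning of occurrence records, Gaussian
    kernel sampling-bias surfaces with bias-weighted background selection,
    pairwise-correlation and jackknife variable screening, threshold-based
    binarisation (maximum sensitivity-plus-specificity and 10th-percentile
    training presence), contraction/expansion change accounting, centroid and
    block-centroid migration-vector analysis, and per-cell limiting-factor
    attribution. Includes raster I/O for ESRI ASCII grids and single-band
    GeoTIFF, and a synthetic climate/occurrence generator with known ground
    truth so the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'grid-io.R'
    'stack.R'
    'synthetic.R'
    'occurrences.R'
    'screening.R'
    'maxent-features.R'
    'maxent-fit.R'
    'dynamics.R'
    'limiting.R'
    'pipeline.R'
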