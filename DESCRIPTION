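Package: vagomorph
Title: Peripheral Nerve Cross-Section Morphometry and Compound Action
    Potential Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative morphometry of segmented peripheral nerve
    cross-sections (fascicle, perineurium and endoneurium areas, Feret
    diameters, circularity metrics, shape-adjusted ellipse diameter
    correction, G-ratio and myelin thickness) and for heuristic prediction of
    single-fiber and compound nerve action potentials recorded with cuff
    electrodes. Includes a documented plain-text contour-table interchange
    format, a synthetic cross-section generator emulating human cervical
    vagus nerve statistics, nonparametric cohort statistics, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    mgcv,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'morphometry.R'
    'segmentation-io.R'
    'cnap.R'
    'synthetic.R'
    'stats.R'
    'cli.R'
    'vagomorph-package.R'
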