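Package: ensembleScope
Title: Detection and Dynamics of Neuronal Ensembles in Binary Activity Rasters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies neuronal ensembles in binary activity rasters from
    calcium-imaging experiments and characterizes their dynamics. Builds a
    weighted functional-connectivity graph over neuron activity vectors with a
    fuzzy nearest-neighbor construction, detects ensembles by leading-eigenvector
    modularity maximization with consensus clustering, validates ensemble
    coactivity against randomness with the Wald-Wolfowitz runs test calibrated
    by two classes of surrogate rasters, extracts significant coactivity peaks
    with a sliding-window dynamic threshold, builds directed ensemble transition
    graphs, and quantifies ensemble firing-rate dynamics with recurrence
    quantification analysis (recurrence rate, determinism, divergence,
    laminarity, and mean white vertical line length). Includes a synthetic
    raster generator with planted ensembles and condition-like presets for
    fully reproducible validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
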