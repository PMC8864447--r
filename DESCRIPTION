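Package: psthComponents
Title: Temporal Response Component Analysis for Peristimulus Time Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, validation, and tracking of temporal response components in
    peristimulus time histograms (PSTHs) of sensory-cortex units recorded across graded
    stimulus intensities. Implements an extended local-maxima algorithm with iterative
    nearest-pair merging to identify response components per unit, a peakiness statistic
    and one-tailed two-sample t test to validate each component against its surrounding
    bins, and a graph-theoretic method that converts the intensity-by-time PSTH matrix
    into a weighted directed grid graph and extracts vertex-disjoint shortest paths
    (Dijkstra with iterative re-weighting) to track components and quantify their
    non-stationarity across stimulus intensities. Includes population-level statistics
    (component-count proportion tables, Kolmogorov-Smirnov comparisons, first-vs-second
    component timing regressions, non-stationarity distributions), a Poisson spike-raster
    simulator with programmable response components and ground-truth output for
    parameter-recovery testing, and a file-mediated analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
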