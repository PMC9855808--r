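Package: iegnet
Title: Immediate Early Gene Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and stress-tests functional connectivity networks from
    regional immediate early gene (IEG) expression densities, such as brain-wide
    c-Fos counts. Region-by-animal density tables are cross-correlated across a
    cohort, thresholded by significance (with optional Benjamini-Hochberg false
    discovery rate filtering and critical-r floors) into binary networks, and
    characterized with graph-theoretic measures (degree, density, global and
    local efficiency, clustering, betweenness, small-world comparison against
    random null models). Robustness tooling implements exhaustive same-size
    subsampling of the cohort to quantify per-edge significance flips and
    p-value variance as a function of group size, and threshold-sensitivity
    scans across alpha levels. A synthetic-cohort generator with known
    ground-truth networks supports calibration and recovery testing, and a
    Cavalieri point-count helper converts raw regional label counts into
    densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    Matrix,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
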