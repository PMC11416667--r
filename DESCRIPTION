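Package: enclavekit
Title: Genealogical Demixing Analytics for Growing Bacterial Monolayer Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the two progeny chains descending from a
    founder cell's first division arrange themselves spatially ("genealogical
    enclaves") in growing bacterial monolayer colonies. Provides a label-free
    lineage tracker for segmented time-lapse label masks (centroid-cutoff
    matching, dummy-centroid division detection, pole-displacement rescue),
    genealogical-enclave geometry (contact graphs, enclave polygons, interface
    length, moving-box Shannon entropy with a permutation null, interface
    curvature and invasion-front widths), nematic orientation-field analysis
    with winding-number topological-defect detection, a coarse-grained
    stochastic lattice model of enclave formation with log-normal division
    clocks and weighted shoving, and a ground-truthed synthetic rod-colony
    generator so that every stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    utils,
    png,
    tiff,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
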