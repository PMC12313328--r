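Package: mechanodc
Title: Dynamic Deformability Cytometry Simulation and Mechanotyping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cells deforming and relaxing as they transit an
    undulating (constriction-cavity-constriction) microfluidic channel,
    renders per-frame binary cell masks, links detections into single-cell
    trajectories, extracts mechanotyping features (relative deformability,
    relaxation and re-deformation slopes, central and Hu moments), trains
    tabular and recurrent sequence classifiers of cell phenotype, and
    converts classifier operating characteristics into expected fold
    enrichment of rare target populations in a sorted sample.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    readr,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
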