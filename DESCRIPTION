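Package: funcphen
Title: Functional Phenotyping of Sensorimotor Cortex in ALS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested analysis pipeline for individualized functional
    phenotyping of the sensorimotor cortex in amyotrophic lateral
    sclerosis (ALS) from task fMRI. Implements robust Shared Response
    Modelling (rSRM) with dual group shared spaces and leave-one-subject-out
    SVM classification, eigenvector centrality mapping and seed-based
    connectivity with stage-wise patient-control contrasts, block-design
    GLM functional localizers, and NIPALS partial least squares regression
    linking voxel-wise functional features to clinical scores, together
    with a synthetic multi-subject BOLD cohort generator so that every
    stage is exercisable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
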