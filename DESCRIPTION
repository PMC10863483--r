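Package: glenoidbl
Title: Semiautomated Glenoid Bone Loss and Stability Quantification from CT Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies anterior glenoid bone loss and the bony shoulder
    stability ratio (BSSR) from CT-derived segmentations of the scapula and
    humerus. Extracts bone surfaces from label volumes (NIfTI/NRRD), isolates
    the glenoid articular region, builds a principal-component anatomical
    frame, fits the inferior best-fit circle, and derives linear (1D), area
    (2D), and concavity-based (3D) bone-loss metrics from mesh projections
    and parallel cross-sections. Includes interrater reliability statistics
    (two-way random absolute-agreement ICC with confidence intervals,
    Landis-Koch interpretation, distribution-gated paired comparisons) and a
    synthetic glenoid phantom generator with closed-form ground truth for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    nortest,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
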