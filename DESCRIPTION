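Package: dynrad
Title: Dynamic Radiomics for Multi-Phase Contrast-Enhanced MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic radiomics analysis of multi-phase
    (dynamic contrast-enhanced) MRI. Extracts a 484-feature static
    radiomics bank (intensity, GLCM/GLRLM/GLSZM/NGTDM texture, and 3D
    wavelet sub-band texture features) per phase, constructs 20 dynamic
    feature types per static feature from the 4-phase trajectory
    (integrated, discrete change-rate, and linear/quadratic/exponential
    curve-fitting features), filters features by segmentation
    reproducibility (ICC), and builds and evaluates static, dynamic and
    dynamic-static logistic radiomics signatures with F-test and LASSO
    feature selection. Includes a synthetic 4-phase phantom cohort
    generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    glmnet,
    pROC,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
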