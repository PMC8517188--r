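Package: planqa
Title: Complexity Analytics and Gamma Passing Rate Modeling for VMAT Patient-Specific QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for volumetric modulated arc therapy (VMAT) patient-specific
    quality assurance analytics. Parses and writes DICOM-RT Plan files into a
    typed control-point model; computes 48 conventional plan-complexity metrics
    and a configurable control-point-resolved ("planomics") histogram feature
    vector; provides a 2-D gamma-index engine with gamma passing rates and
    pass/fail decisions at clinical action limits; implements a stability
    feature-selection pipeline (zero-variance removal, repeated univariate
    F-screening, minimum-redundancy-maximum-relevance) and a repeated
    train/test evaluation protocol for gradient-boosted gamma-passing-rate
    regression and ridge pass/fail classification. Includes a synthetic VMAT
    cohort generator so the full pipeline is exercisable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    glmnet,
    xgboost,
    pROC
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conventional.R'
    'dicom.R'
    'gamma.R'
    'machine.R'
    'models.R'
    'planomics.R'
    'planqa-package.R'
    'rtplan.R'
    'selection.R'
    'synthcohort.R'
    'utils.R'
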