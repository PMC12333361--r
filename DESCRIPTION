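Package: cidnpscreen
Title: Feature-Based Screening of Steady-State Photo-CIDNP Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to connect molecular features of indole, amino-acid and
    phenol derivatives to steady-state photochemically induced dynamic nuclear
    polarization (photo-CIDNP) signal-to-noise enhancement (SNE). Implements
    condensed nucleophilic Fukui indices from atomic charge tables, the
    geminate polarization probability Q from hyperfine couplings and g-factor
    differences, Kaptein net-effect sign rules for electron-transfer versus
    proton-coupled electron-transfer mechanism assignment, within-molecule
    site ranking by reactivity descriptors, coarse-grained trend fits, PCA and
    ANOVA/Tukey statistics, and repeated random-split classification and
    regression with feature importances. A synthetic compound-library
    generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    nnet,
    glmnet,
    xgboost,
    ranger,
    e1071,
    caret,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
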