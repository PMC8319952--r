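Package: suboar
Title: Sub-OAR Ring Volumes and Support-Vector Prediction of D2cm3 in
    Cervical Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the D2cm3 dose to organs at risk (bladder, rectum,
    sigmoid colon, small intestine) in tandem-and-ovoid brachytherapy for
    cervical cancer.  The high-risk clinical target volume (HR-CTV) is
    expanded into concentric 0.5 cm ring shells with an exact anisotropic
    Euclidean distance transform; the intersection volumes of each ring with
    each organ at risk ("sub-OAR" volumes) are used as features for
    per-organ epsilon-support-vector regression with a radial basis function
    kernel, predicting the dimensionless ratio D2cm3/Dprescription.  Includes
    DVH-based dose metrics (D2cm3, D90, EQD2), per-fraction planning
    constraints, a seeded synthetic pelvic-phantom cohort generator with a
    point-source dose engine, model evaluation statistics (MSE, R-squared,
    delta, Pearson correlation, paired t-test), and a plan quality-assurance
    pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
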