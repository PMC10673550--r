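Package: cilFAHFA
Title: Chemical Isotope Labeling LC-MS Profiling of FAHFA Regioisomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for profiling fatty acid esters of hydroxy
    fatty acids (FAHFAs) by chemical isotope labeling LC-MS with the
    DMED/d4-DMED carboxyl labeling reagent pair. Generates MRM transition
    tables from fragmentation rules (neutral loss of dimethylamine plus
    water, 63/67 Da), screens co-eluting light/heavy peak pairs with a
    4.0251 Da precursor offset, annotates ester-bond positions by retention
    match to authentic standards or by log10 retention-index regression,
    quantifies analytes as peak-height ratios to heavy internal standards,
    and runs the differential workflow used for paired tumor/normal tissue
    studies: paired t-tests with Benjamini-Hochberg FDR, fold changes,
    volcano filtering, OPLS-DA with VIP scores and permutation testing,
    Venn intersection, and multivariate ROC biomarker panels. Includes a
    synthetic-data generator that emulates the study design (72 isomers in
    9 families, 24 patient pairs, effect sizes and p-value-calibrated noise).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
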