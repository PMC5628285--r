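Package: cesdcat
Title: Psychometric Evaluation and Computerized Adaptive Testing for the
    CES-D Depression Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and adaptively administering the Center for
    Epidemiologic Studies Depression Scale (CES-D) and similar ordered-category
    questionnaires.  Implements scale-level evaluation (Cronbach's alpha,
    one-factor confirmatory factor analysis with CFI/TLI/RMSEA, Mokken
    scalability with iterative item removal), calibration and diagnostics under
    Samejima's graded response model (marginal maximum likelihood estimation,
    Yen's Q3 local-dependence statistic, testlet formation, stratified item
    fit, ordinal-logistic-regression differential item functioning), a
    maximum-Fisher-information computerized adaptive testing engine with a
    standard-error stopping rule, and decile-stratified simulation studies of
    adaptive-test performance.  A synthetic response generator with controlled
    multidimensionality, local dependence and differential item functioning
    makes the full pipeline testable without access to respondent-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
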