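Package: ugibscores
Title: Pre-Endoscopic Risk Scores and Mortality Analytics for Upper
    Gastrointestinal Bleeding Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for thirteen pre-endoscopic prognostic scores
    (Glasgow-Blatchford and its modified variant, pre-endoscopic Rockall and
    Baylor, AIM65, T-score, N-score and a hematemesis-stratified variant,
    H3B2, MAP, Iino, the International Bleeding Score, and the Charlson
    comorbidity index) and three cirrhosis-severity scores (Child-Pugh-
    Turcotte, a creatinine-augmented variant, and MELD), computed from raw
    clinical and laboratory fields of tabular patient records.  Companion
    analytics evaluate in-hospital-mortality discrimination: midrank AUC
    with DeLong confidence intervals, Youden-index cutoffs, Swets accuracy
    bands, and 2x2 contingency odds ratios with Woolf intervals and Wald
    tests.  A latent-severity synthetic cohort generator emulates the
    three-etiology case mix of an upper-GI-bleeding admissions population
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
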