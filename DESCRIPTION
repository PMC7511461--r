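Package: laceroc
Title: Age-Specific LACE Index Thresholds from Two-Graph ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the LACE hospital readmission risk index
    (Length of stay, Acuity, Charlson comorbidity, Emergency department
    visits; total score 0-19) as a predictor of post-discharge mortality and
    frequent readmission. Computes the Charlson comorbidity index from ICD-10
    diagnosis codes using the Quan 2005 coding algorithm, scores LACE
    components from episode records, estimates ROC curves with Hanley-McNeil
    or DeLong confidence intervals, derives equal-error decision thresholds
    and intermediate ranges by two-graph ROC analysis, reports positive and
    negative likelihood ratios, and runs age-stratified study pipelines with
    threshold-impact summaries. Includes a calibrated synthetic cohort
    generator so the full analysis chain can be exercised and tested without
    access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
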