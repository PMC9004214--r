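Package: oatcascade
Title: Cascade-of-Care Analysis for Opioid Agonist Treatment Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs opioid agonist treatment (OAT) episodes from
    longitudinal dose records using medication-specific disqualifying gaps
    (5 days for methadone, 6 for buprenorphine/naloxone), classifies patients
    into four retention stages of a cascade of care (under 90 days, 90-365
    days, one to two years, over two years), derives patient-level covariates
    (urine-drug-screen positivity quadrants, rurality/region strata, dose
    summaries), and estimates crude and adjusted multinomial logistic odds
    ratios of stage membership with Wald confidence intervals. Includes a
    seeded synthetic electronic-medical-record generator with known ground
    truth so every pipeline stage has an exact recovery test, and a pipeline
    orchestrator that writes all report artifacts with an exclusion ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
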