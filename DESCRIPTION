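Package: behavnet
Title: Laboratory-Free Type 2 Diabetes Risk Scoring and Behavioral
    Influence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A dual-analytic framework for laboratory-free Type 2 Diabetes
    Mellitus (T2DM) risk analysis. Implements Cox proportional hazards risk
    scoring with decision-tree stratification and Kaplan-Meier validation,
    together with neural-network connection-weight influence analysis
    (Garson-style effective weights) that maps directed behavioral
    relationships among diet, sleep, psychosocial and demographic variables,
    and compares their network structure between healthy and diabetic
    cohorts.  Ships a synthetic-cohort generator emulating the 18-predictor
    behavioral schema of a large prospective biobank so every stage of the
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    rpart,
    stats,
    survival,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
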