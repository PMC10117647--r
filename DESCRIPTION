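Package: locorecur
Title: Stochastic Multistage Model of Cancer Initiation and Locoregional
    Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates multistage carcinogenesis, surgical resection and
    locoregional recurrence in a fixed-size tissue. Normal and premalignant
    cells follow a Moran process (well-mixed or on a 2D lattice with wall
    boundaries); malignant cells follow a supercritical branching process
    with a deterministic-growth shortcut once the tumor is large. Includes
    dominance/co-dominance classification of tissue composition at
    detection, Kaplan-Meier estimation and log-rank comparison of
    recurrence times, percentile-grid survival-curve fitting by random
    parameter search, synthetic disease-free-survival cohort generation,
    and a bundled table of fitted tumor-specific carcinogenic profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
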