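Package: pvsignal
Title: Disproportionality Signal Mining and Severe-Event Risk Modelling
    for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FAERS-style
    spontaneous adverse-event reporting data: parsing of quarterly
    dollar-delimited report tables, case deduplication and deleted-case
    handling, drug-name normalization, reporting odds ratio (ROR) and
    proportional reporting ratio (PRR) disproportionality statistics with
    dual signal-screening criteria, comparison of flagged events against a
    product label, and univariate/multivariate logistic regression of
    severe-outcome risk factors. Includes a calibrated synthetic
    spontaneous-reporting-system generator with known ground truth
    (injected per-event reporting odds ratios, duplicate and deletion
    structure, a logistic severity model) so the full pipeline can be
    exercised and validated without access to a reporting-system archive,
    plus an audit tool that reconstructs 2x2 contingency tables from
    published (count, ROR, PRR, chi-square) rows.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
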