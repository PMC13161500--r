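Package: sgbal
Title: Propensity Score Weighting with Exact Subgroup Covariate Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates inverse-probability-of-treatment weights that achieve
    exact covariate mean balance not only in the overall sample but within
    pre-specified (possibly overlapping) subgroups, by solving covariate
    balancing estimating equations derived from a globally concave scoring-rule
    loss. Includes a nonparametric extension that balances Gaussian kernel
    principal-component features with balance-driven bandwidth selection,
    weighted standardized-difference balance diagnostics, Hajek subgroup
    treatment-effect estimation for the ATE and the ATT, standard comparator
    propensity-score methods, and a Monte-Carlo simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
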