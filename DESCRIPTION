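Package: misdiagpower
Title: Power of Case-Control Association Studies under Case Misdiagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo tools to quantify how misdiagnosis of cases (a
    latent mixture of genuine and apparent patients) erodes the power of
    Pearson's chi-squared test in case-control association studies, with
    an optional layer of imperfect sensitivity/specificity in the binary
    classification of the causal factor (e.g. serological cut-offs).
    Provides closed-form exposure-probability formulas, product-binomial
    and latent augmented-table simulators, seeded power curves over
    misdiagnosis-rate grids, antitonic-smoothed threshold search for the
    largest misdiagnosis rate retaining a target power, scenario grid
    runners, bundled parameter sets for two published ME/CFS studies, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
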