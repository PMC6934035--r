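Package: statrace
Title: State-Trace Analysis of Sentence Rating Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether two kinds of sentence ratings --
    overall acceptability and instructed grammaticality -- are driven by a
    single latent well-formedness factor. Implements weighted isotonic
    regression by pool-adjacent-violators, coupled monotonic regression over
    a common latent order (exact enumeration on small instances, seeded
    local search at scale), and a bootstrap dimensionality test on the
    state-trace plot. Includes a seeded simulator for Likert rating
    experiments with controllable latent correlation, the participant
    exclusion pipeline typical of crowd-sourced rating studies, and
    descriptive summaries (condition contrasts, response extremity,
    standardized response times, per-item difference distributions).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
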