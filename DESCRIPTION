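Package: remer
Title: Removal Models Accounting for Temporary Emigration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Abundance estimation from removal count data when part of the
    population is temporarily unavailable for capture. Implements the
    robust-design multievent removal model (RMER), its single-secondary
    special case (MER) and an integrated multi-population extension (IRMER)
    as hidden Markov product-multinomial likelihoods, together with
    constraint systems for the initial-state, transition and capture
    parameters, maximum-likelihood fitting with restarts, Hessian and
    nonparametric-bootstrap uncertainty, AIC model ranking, a classic
    geometric (Moran-Zippin) removal baseline, a data simulator emulating
    the models' data-generating process, and numeric parameter-redundancy
    and near-redundancy diagnostics based on the rank of the Jacobian of
    the cell-probability exhaustive summary.
License: MIT + file LICENSE
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
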