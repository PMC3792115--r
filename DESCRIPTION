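Package: popsize
Title: Bayesian Population Size Inference from Count Data with Discrete
    Uniform Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the size n of a finite population of homogeneously
    dispersed objects from one or more count measurements taken on known
    sampling fractions, using a binomial likelihood and a discrete uniform
    (maximum-entropy) prior. Exact posterior distributions are computed
    under sampling with replacement (via a nested-sum reduction of the
    semi-infinite normalizing constant) and without replacement (where the
    posterior is a shifted negative binomial depending on the data only
    through the total count and total fraction). Includes maximum a
    posteriori estimates, equal-tailed and highest-posterior-density
    credible intervals, a Gamma-Poisson conjugate reference method and
    Jensen-Shannon divergence machinery for method comparison, seeded
    simulators of both sampling schemes for coverage experiments, and a
    power-law survival-curve fit for time-course enumeration data such as
    viable plate counts.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
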