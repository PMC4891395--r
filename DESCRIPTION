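Package: corbf
Title: Bayes Factor Tests for the Presence or Absence of a Pearson Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A suite of Bayes factor hypothesis tests for the Pearson
    product-moment correlation under the bivariate normal model. The data
    enter every test only through the sample size n and the sample
    correlation r, via the exact reduced likelihood of r with the location
    and scale nuisance parameters integrated out. Supported tests: the
    default two-sided test with a uniform prior on the correlation, the
    one-sided (sign-restricted) test, a prior-sensitivity analysis over the
    stretched-beta family, interval null hypotheses, sequential updating
    with the multiplication rule for Bayes factors, and replication Bayes
    factors in which the posterior from an original study serves as the
    prior for a replication attempt. Posterior densities, Savage-Dickey
    density-ratio cross-checks, credible intervals, a bivariate-normal
    simulator for calibration experiments, and a command-line interface are
    included, together with the published summaries of nine replication
    studies of the loneliness/physical-warmth correlation as a worked
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
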