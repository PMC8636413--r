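Package: lw25
Title: Summed-Score Likelihoods and Score-Combination Posteriors for
    Two-Tier Item Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recursive computation of summed-score likelihoods for
    hierarchical (bifactor and two-tier) item factor models, including the
    Lord-Wingersky algorithm for item clusters (version 2.0) and its
    extension to observed score combinations (version 2.5).  Produces
    summed-score to EAP conversion tables, bivariate posteriors of primary
    and specific latent dimensions conditional on cluster score versus rest
    score pairs, and three downstream procedures: classification of
    posterior mass against achievement cut scores, screening of subscores
    for reporting via probability-weighted regression prediction bands, and
    detection of aberrant score combinations through discrete high-density
    regions.  Includes worked-example and operational-assessment parameter
    fixtures, a synthetic model generator, CSV/JSON interchange, a response
    pattern enumeration oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
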