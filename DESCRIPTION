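Package: cotsdetect
Title: Detectability and Abundance Estimation for Crown-of-Thorns Starfish Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the abundance and detectability of
    crown-of-thorns starfish (Acanthaster spp.) from intensive transect
    surveys. Implements closed-population abundance estimation by depletion
    (removal) sampling and by Lincoln-Petersen mark-recapture (with an
    optional Chapman bias correction), per-transect and size-class
    detection proportions and density conversions, and binomial-logit
    generalized linear mixed models with a single site-level random
    intercept fitted by adaptive Gauss-Hermite quadrature, ranked by AICc
    with Type-II Wald tests. A survey simulator generates populations and
    depletion or mark-recapture survey schedules with size-, time-, zone-
    and aspect-dependent detection so every estimator can be validated by
    parameter recovery without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
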