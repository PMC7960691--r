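Package: hearburden
Title: Severity-Split Hearing Loss Prevalence and Disability Burden Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a global burden of disease style
    estimation pipeline for bilateral hearing loss. Survey prevalence data (or a
    fully synthetic stand-in generated by the package) are harmonised to a
    reference case definition by sex splitting, severity-threshold crosswalks and
    age splitting; nested prevalence models with sum-to-one and envelope squeezes
    estimate severity-specific prevalence surfaces; hearing-aid use, cause
    attribution and tinnitus co-occurrence split the estimates into health
    states; years lived with disability are computed with draw-level uncertainty
    propagation; and prevalence is forecast to mid-century with a region-by-year
    regression on a cubic age spline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    mgcv,
    metafor,
    MASS,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
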