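Package: picograze
Title: Growth and Grazing Mortality of Picoplankton Across Ocean
    Productivity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-treatment dilution experiments on marine
    picoplankton (heterotrophic bacteria, Prochlorococcus, Synechococcus,
    and photosynthetic picoeukaryotes). Simulates Lagrangian cruise
    surveys across a primary-production gradient, estimates instantaneous
    growth and microzooplankton grazing mortality from paired
    diluted/undiluted bottle incubations, fits Model II (major-axis)
    regressions of rates and mortality ratios against primary production
    over overlapping gradient segments with permutation significance, and
    computes shared-predation projections (scaled mortality, daily
    population decline, time to local extinction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
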