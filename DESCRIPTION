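Package: mammosim
Title: Microsimulation of Breast Cancer Screening Regimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cohort microsimulation of breast cancer natural history and
    mammography screening. Simulates per-woman life histories (cancer
    initiation, Gompertz tumor growth, nodal and distant spread, screen and
    clinical detection, stage-specific survival, competing mortality from a
    life table) under configurable screening regimens, using common random
    numbers so that between-regimen contrasts are low variance and stage-shift
    mechanics are exact. A reporting layer turns per-regimen outcomes - or
    published per-regimen outcome tables - into mortality reductions, life
    years saved, number needed to screen, stage distributions, recall and
    negative-biopsy burdens, participation-weighted mixtures and national
    scalings.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
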