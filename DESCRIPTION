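Package: biocathode
Title: Electron Accounting and Community Profiling for Cathodic Enrichment Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microbial electrosynthesis and
    electro-fermentation enrichments on polarized cathodes. Extracts
    biocoulombs and fold-increase statistics from chronoamperometry traces,
    converts metabolite and chemical-oxygen-demand measurements into
    electron equivalents, builds per-reactor multi-donor electron budgets
    with coulombic efficiencies and scenario classification, evaluates the
    thermodynamic feasibility of cathodic hydrogen evolution via the Nernst
    equation, computes cumulative microbial-activity scores, and renormalizes
    16S amplicon count tables by qPCR-derived bacteria/archaea proportions.
    Includes a budget-consistent synthetic reactor generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
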