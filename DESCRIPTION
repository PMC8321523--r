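Package: persevol
Title: Serial-Passage Evolution of Antibiotic Persistence Under Population Bottlenecks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and analysis of experimental evolution of
    bacterial antibiotic persistence under serial-transfer regimes with
    population bottlenecks. Provides a Wright-Fisher-style serial-passage
    simulator (daily bactericidal treatment, dilution bottleneck, regrowth
    with de novo beneficial mutations), biphasic time-kill survival curves,
    sigmoidal adaptation-trajectory fitting on log10 persister fractions,
    growth-curve competition coefficients from areas under the curve,
    relative fitness from head-to-head frequency assays, a deterministic
    bottleneck-corrected mutant-spread recurrence, barcoded knockout-library
    selection simulation and count-table analytics (control-design
    normalization, enrichment and depletion calls with growth-control
    filtering, diversity and between-replicate heterogeneity metrics), and a
    small statistics toolkit with exact small-sample Spearman permutation
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
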