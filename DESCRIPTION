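Package: midflux
Title: Stable-Isotope Tracer Flux Analysis from Mass Isotopologue
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of [1,2-13C2]-glucose tracing experiments in cultured
    cells from GC-MS mass isotopologue distributions (MIDs). Provides
    natural-isotope-abundance correction of selected-ion-monitoring MID
    vectors, consumption-and-release (CORE) rates of medium metabolites
    normalized to cell exposure, estimation of the glycolytic lactate flux
    and the glucose fate partition, the oxidative/non-oxidative pentose
    phosphate pathway split from ribose m1/m2 labeling, binomial mass
    isotopomer distribution analysis (MIDA) of palmitate and stearate for
    lipogenic acetyl-CoA enrichment and fractional synthesis, best-cutoff
    Kaplan-Meier survival analysis with log-rank testing and expression
    correlation, and a forward label-propagation simulator with known
    ground truth for validating every estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    survival,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
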