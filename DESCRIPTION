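Package: csiaray
Title: Compound-Specific Isotope Analysis of Microbial Hydrocarbon Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compound-specific stable isotope analysis (CSIA) of
    microbial hydrocarbon biodegradation in anoxic systems. Fits the
    linearized Rayleigh distillation model to carbon and hydrogen isotope
    time series to estimate bulk enrichment factors with confidence
    intervals, computes dual-isotope plot slopes (lambda) and apparent
    kinetic isotope effects (AKIE) with position-specific corrections,
    classifies results against a packaged literature compilation of benzene
    enrichment factors by redox condition, and provides microcosm
    degradation-kinetics bookkeeping (control- and internal-standard
    normalized residual curves, lag and halt detection, biomass doubling
    times). A forward simulator of BTEX microcosms generates concentration
    and isotope trajectories with realistic measurement noise so that every
    stage of the pipeline can be exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
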