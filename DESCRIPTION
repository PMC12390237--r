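Package: dualtracer
Title: Stable-Isotope Dual-Tracer Bioaccumulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stable-isotope dual-tracer metal
    bioaccumulation experiments in aquatic animals, in which one isotope
    labels the waterborne exposure route and a second isotope labels the
    dietary route. Provides tidy-table input/output and validation for
    exposure designs, a synthetic experiment generator with multiplicative
    measurement noise, background subtraction and feeding-window scaling of
    dietary measurements, influx-rate estimation by linear regression of new
    accumulation against exposure time, waterborne-versus-dietary source
    apportionment with bootstrap confidence intervals, and supporting
    statistics (one-way ANOVA with compact letter displays, paired t-tests,
    QC checks for tracer specificity and spike recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
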