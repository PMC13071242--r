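Package: SoapShift
Title: Solvent-Aware Machine Learning of 1H NMR Chemical Shifts for Zinc
    Complexes from SOAP Descriptors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts solvent-dependent 1H NMR chemical shifts of zinc(II)
    coordination complexes with machine learning on smooth overlap of atomic
    positions (SOAP) descriptors. Provides an exact SOAP power-spectrum
    engine (Gaussian-type and polynomial radial bases), k-means++
    representative-subset selection of chemical space with Kolmogorov-Smirnov
    and diversity-ratio validation, dielectric-constant solvent encoding,
    molecule-level train/test splitting with grouped cross-validation over a
    registry of regression backends, TMS-referenced shielding-to-shift
    conversion, and a synthetic-fixture generator so the complete pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    xgboost,
    ranger,
    e1071,
    kernlab,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
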