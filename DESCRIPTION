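Package: tracedigest
Title: Trace-Element Speciation Dynamics in Anaerobic Digestion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase kinetic simulator of anaerobic digestion that couples
    the IWA Anaerobic Digestion Model No. 1 (ADM1) biochemistry to the
    geochemistry of trace metals (Fe, Ni, Co) and alkali-earth metals (Ca, Mg):
    kinetic mineral precipitation and dissolution switched by the saturation
    state, EDTA and volatile-fatty-acid complexation closed by stability
    constants, reversible second-order sorption onto binding sites carried by
    biomass, inert matter and FeS, charge-balance pH, liquid-gas transfer and
    a trace-metal dose-response factor on methanogenic kinetics. Batch and
    continuous (CSTR) reactors are supported, with preset simulation scenarios,
    tidy trajectory output and per-metal speciation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
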