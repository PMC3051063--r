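Package: nfkbdrug
Title: Drug Inhibition Profiling for the TNFa-Induced NFkB Pathway in
    Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A 26-species mass-action ordinary-differential-equation model of
    TNFa-induced NFkB signaling in multiple myeloma cells, with tools to fit
    its 21 free rate constants to sparse IkB/NFkB time-course data by
    multistart Hooke-Jeeves pattern search, perform local parameter
    sensitivity analysis on the steady nuclear NFkB output, inject four
    mechanistically distinct inhibitors (TNFa sequestration, IKK
    sequestration, proteasome inhibition, NFkB sequestration) into the
    network, and predict single-drug inhibition profiles, Bliss
    combination-index synergy maps, and Loewe isobolograms for two-drug
    combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    MASS,
    stats,
    utils,
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
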