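Package: levogut
Title: Multiscale Gastrointestinal Absorption Modeling of Levodopa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates gastrointestinal absorption and whole-body
    disposition of levodopa with a physiologically based pharmacokinetic
    model whose oral-absorption component is a compartmental transit
    (ACAT-type) chain, coupled at fixed time steps to constraint-based
    (flux balance analysis) models of the small-intestinal enterocyte in
    each of seven intestinal segments. Supports prandial-state physiology,
    dietary amino-acid competition and trans-stimulation at shared
    transporters, parameter estimation from plasma concentration data,
    local sensitivity ranking, diet-scenario comparison scored by area
    under the curve above efficacy thresholds, and flux-balance ranking
    of amino acids by their effect on brain levodopa delivery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    xml2,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
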