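Package: cvepr
Title: Code-Modulated Visual Evoked Potential BCI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for code-modulated visual evoked potential (c-VEP)
    brain-computer interfaces: generation and analysis of p-ary
    maximal-length sequences via linear-feedback shift registers,
    grey-level stimulus scheduling at 60/120/240 Hz refresh rates,
    simulation of multichannel EEG with code-locked evoked responses,
    filter-bank canonical-correlation template matching with an online
    sliding-window decision rule, leave-one-block-out cross-validation,
    information transfer rates, and simulated copy-spelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
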