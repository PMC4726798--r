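Package: loadsim
Title: Spiking-Network Simulations of Perceptual Load and Distractor Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates visual selective attention in letter-search flanker
    tasks with a two-stage spiking neural model. Search displays are generated
    and rendered in-package, passed through an Itti-Koch saliency analysis that
    sets the initial firing rates of Poisson spike-train populations, and then
    evolved under all-to-all competitive inhibition, top-down spatial priming,
    and a synchrony-based control module that amplifies stimuli resembling the
    target templates. A two-node working-memory readout yields per-trial
    response latency and accuracy, from which perceptual-load, spatial-cueing,
    central-distractor, and dilution effects on distractor interference are
    summarized.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
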