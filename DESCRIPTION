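Package: glosstrans
Title: Gloss Perception Through Transparent Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gloss constancy behind partially transmissive
    layers. Implements episcotister (Metelli) compositing of luminance images
    with contrast and histogram diagnostics, maximum-likelihood conjoint
    measurement (independent, additive and full observer models with nested
    likelihood-ratio tests), maximum-likelihood difference scaling for
    perceptually equal stimulus spacing, and the analysis of asymmetric
    matching errors including their relation to Michelson contrast. Ships
    simulators for paired-comparison and matching experiments and a
    procedural generator of glossy-object stimuli, so the full pipeline runs
    end-to-end on synthetic observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
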