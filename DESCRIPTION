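Package: isobarrier
Title: Reproductive Isolation Barrier Quantification for Flower Colour Forms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies reproductive isolation (RI) between co-occurring
    flower colour forms from field and experimental data. Computes
    per-barrier RI indices and their directional asymmetry (phenological
    overlap, pollinator foraging, pollinia-pistil interaction, fruit
    production, seed development), composes barriers sequentially into
    total RI with absolute and relative per-barrier contributions,
    derives Gegear's floral constancy index from pollinator foraging
    sequences, and places floral reflectance spectra in the hymenopteran
    colour hexagon (quantum catches, von Kries adaptation, receptor
    excitation, chromatic distance against a just-noticeable-difference
    threshold). Includes a synthetic-data generator emulating the
    statistical structure of the field inputs, file readers and writers
    for all input formats, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
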