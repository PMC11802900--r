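Package: rnlvis
Title: Receptor-Noise-Limited Visual Modelling of Mimetic Wing Colors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling color discriminability of butterfly wing
    patches through insect and avian visual systems. Reads, resamples,
    smooths and aggregates reflectance spectra; evaluates A1 visual-pigment
    absorbance templates and estimates peak absorbance (lambda-max) from
    difference spectra and pupillary spectral sensitivities by least
    squares; classifies blue-opsin spectral tuning from the residue at
    alignment site 195; computes quantum catches, von Kries adapted
    receptor signals, receptor-noise-limited chromatic and achromatic
    distances (just-noticeable differences), and chromaticity coordinates
    in Maxwell-triangle and tetrahedral color spaces; and bootstraps color
    distances between stimulus groups with percentile confidence
    intervals. Includes seeded generators for synthetic wing reflectance,
    difference-spectrum, pupillometry and alignment data so the full
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
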