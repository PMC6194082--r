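Package: sipgrad
Title: DNA Stable-Isotope Probing Gradient Analysis and Isotope Mass Balance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of DNA stable-isotope probing (SIP)
    experiments with 13C-labelled substrates. Implements the carbon isotope
    mass balance converting delta-13C of particulate organic carbon into
    microbial 13C assimilation rates; analysis of CsCl buoyant-density
    gradient fractions (peak detection, 13C versus 12C profile separation,
    representative heavy/light fraction selection and incubation-time
    selection); community comparison statistics (equal-depth subsampling,
    Bray-Curtis dissimilarity, Shannon diversity, group-average clustering,
    NMDS ordination, ANOSIM); classification of substrate-incorporating
    OTUs into ecological response types; in-silico terminal restriction
    fragment (T-RF) digestion; and a fully seeded simulator of the whole
    SIP experiment with planted ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
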