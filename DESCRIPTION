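Package: hlascore
Title: Bimodal Expression Fingerprinting for Sample Annotation Quality
    Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovers bimodally expressed "fingerprinting" probe sets in
    expression matrices using Hartigan's dip statistic with Monte-Carlo
    empirical p-values, scores samples against binary haplotype marker
    panels (the HLA-score) and a transcript-based sex panel (REDKX), and
    flags intra-donor annotation inconsistencies such as sample mix-ups.
    Includes a synthetic-data generator emulating donor-level bimodal
    marker states and a command-line interface for the discover, score
    and simulate steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
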