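Package: degradome
Title: Motif-Architecture Mapping of a Fungal Protease Degradome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of the Aspergillus niger protease repertoire
    (degradome) from conserved active-site motif architectures. Provides a
    parser and scanner for the compact protease motif notation (wildcards,
    alternations, bounded spacers), a machine-readable MEROPS-style rule
    catalogue with a 232-entry protease inventory and checksum validation,
    per-sequence class/clan/subfamily assignment with active,
    putatively-inactive and non-peptidase-homologue calls, metallopeptidase
    tribe reassignment by active-site architecture, consensus secretome
    voting over multiple localization predictors, EC-bucket and composition
    statistics at printed precision, a seeded synthetic-data generator with
    planted architectures and catalytic-residue knockouts, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
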