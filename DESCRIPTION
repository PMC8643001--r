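Package: cleanburden
Title: Cleanroom Bioburden Analysis from Amplicon Surveys and Spore Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating and dissecting microbial bioburden in
    spacecraft-assembly cleanrooms. Implements negative-control-based
    contaminant flagging and rarefaction of 16S sOTU feature tables,
    phylogenetic hidden-state prediction of sporulation ability with
    leave-one-out average-precision evaluation, compositional log-ratio
    statistics including spatial-gradient correlation against distance from
    the cleanroom entrance, spore-category read accounting, and plate-count
    arithmetic converting NASA-standard-assay spore counts to areal viable
    bioburden via the Space Studies Board ratio. A synthetic-study generator
    reproduces the statistical structure of a multi-session, multi-location
    floor survey (PMA-treated/naive pairs, field/negative/extraction
    controls, spiked reagent contaminants, phylogenetically conserved spore
    traits) so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
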