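Package: cytosweep
Title: Cytoplasmic Incompatibility Invasion Dynamics and Mitochondrial
    Hitchhiking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic discrete-generation models of a cytoplasmic
    incompatibility (CI) inducing Wolbachia strain invading an already
    infected host population while mitochondrial haplotypes hitchhike,
    with paternal, heritable-horizontal and somatic-horizontal
    transmission extensions; travelling-wave transition-zone widths and
    dispersal lower bounds; stratified infection-by-haplotype survey
    statistics with exact tests; in-silico PCR-RFLP haplotyping of COI
    amplicons; and synthetic survey and sequence generators so the whole
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
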