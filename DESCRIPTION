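Package: dgrscan
Title: Detection and Analysis of Diversity-Generating Retroelements in
    Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects diversity-generating retroelement (DGR) cassettes in
    phage and bacterial genomes: repeat-pair discovery with adenine-aware
    alignment scoring, template/variable repeat orientation by adenine
    bias, IMH/IMH* boundary detection, reverse-transcriptase
    identification, cassette architecture classification across genome
    cohorts, exact combinatorial A-to-N diversity counts, variable-repeat
    consensus logos, and a synthetic planted-cassette genome generator
    with machine-readable ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
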