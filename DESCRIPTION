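Package: dartpop
Title: Population Structure, Diversity and Linkage Disequilibrium for
    Dominant Marker Panels
Version: 0.1.0
Authors@R:
    person("dartpop", "developers", email = "dartpop@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for panels of biallelic dominant markers
    (presence/absence calls, e.g. DArT) scored on inbred lines with a
    genetic map: modified Rogers' distances and principal coordinate
    analysis, simple-matching relatedness summaries, polymorphic
    information content profiles along chromosomes, sliding-window
    allele-frequency divergence scans between subpopulations, and
    linkage disequilibrium decay characterisation with a
    population-specific significance threshold derived from unlinked
    loci.  Includes a founder-mosaic simulator that generates marker
    panels with known ground truth for end-to-end validation, and a
    command-line interface wiring all stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
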