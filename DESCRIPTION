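Package: erscan
Title: Selection Scans for Two-Founder Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies selection signatures in two-founder
    evolve-and-resequence (E&R) experiments run under two environmental
    regimes. Reads Pool-Seq allele counts in PoPoolation2 sync format at
    founder-diagnostic marker SNPs, averages focal-founder allele
    frequencies in non-overlapping SNP windows, tests windowed allele
    frequency changes against a neutral null built from Wright-Fisher
    forward simulations with recombination, contrasts the response between
    regimes with a per-window linear model, and assigns each window to one
    of six selection-response classes (drift only, change in one regime
    only, no regime effect, different magnitude, different direction).
    Includes a synthetic-experiment generator with truth-labelled selection
    targets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
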