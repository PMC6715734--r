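Package: ncomap
Title: Crossover and Non-Crossover Gene-Conversion Mapping in Hybrid Mouse Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and analysis of meiotic crossover (CO) and
    non-crossover (NCO) gene-conversion events from multi-generation
    hybrid-mouse genotype data. Provides a hidden Markov model for
    background-ancestry inference, CO/NCO event calling with a
    false-positive filter cascade, composite-likelihood estimation of
    gene-conversion tract lengths with block-bootstrap confidence
    intervals, Poisson-noise-corrected correlations of binned
    recombination rates, hotspot-symmetry analyses from allele-specific
    ChIP enrichment, a two-pathway model of GC-biased gene conversion,
    detection-power simulation, and a synthetic-data generator emulating
    an F0-to-F5 intercross so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    vcfR,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
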