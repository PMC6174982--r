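Package: posq
Title: Structure-Based Surface Patch Screening of Protein Expressability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens protein structures for surface features associated with
    poor secretion in recombinant expression systems. Computes the maximal
    positive electrostatic-potential surface patch (PosQ) from a
    finite-difference linearized Poisson-Boltzmann calculation contoured at
    25 mV, and the maximal nonpolar-to-polar solvent-accessible-surface
    patch ratio over 13 Angstrom atom neighbourhoods. Includes
    sequence-engineering operations (domain swap, region replacement,
    global alignment with chemical annotation) for designing
    secretion-rescued chimeras, and a synthetic-structure generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
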