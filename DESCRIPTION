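Package: galphakin
Title: Nucleotide-Cycle Kinetics and RGS-Coupling Analysis for Plant G-Protein Alpha Subunits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling and analysis of the heterotrimeric G protein
    nucleotide cycle for plant Galpha subunits. Provides closed-form and
    ODE-based simulators for GTPgammaS binding, single-turnover and
    steady-state GTP hydrolysis, intrinsic tryptophan fluorescence under a
    finite GTP pool, and 1:1 Langmuir surface plasmon resonance sensorgrams;
    nonlinear least-squares fitters to recover exchange, hydrolysis and
    binding rate constants from assay time courses; derived statistics
    (steady-state percent GTP-bound occupancy, rate-limiting step,
    self-activation classification, GAP fold-acceleration, affinity fold
    change); and sequence tools that map the switch-I RGS-coupling
    determinant onto Galpha sequences and compute domain-wise Nei-Gojobori
    dN/dS from paired coding sequences. Seeded synthetic-data generators make
    the full simulate-fit-profile pipeline reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
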