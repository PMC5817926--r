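Package: foldclamp
Title: Chaperone-Modulated Mechanical Protein Folding Under Force Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing and simulating single-molecule force-clamp
    refolding experiments on polyproteins in the presence of Hsp40/Hsp70
    chaperones. Implements a deterministic five-state kinetic model of a
    substrate domain (folded, extended free/bound, collapsed free/bound)
    under piecewise-constant force, an exact stochastic (Gillespie) twin
    that renders noisy staircase extension traces, change-point step
    detection and refolding-yield estimation with bootstrap errors,
    chi-square fitting of chaperone binding constants (kon, koff, Kd),
    a Ramachandran dihedral-remodeling free-energy estimator built on
    von Mises mixtures, and scanners for the Hsp40/DnaJ substrate
    consensus motif and DnaK-style hydrophobic patches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    lhs,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
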