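Package: fractorun
Title: Simulation and Deterministic Recurrence for Biased Fractionation
    After Whole Genome Duplication
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the loss of duplicate genes (fractionation) on a pair of
    homeologous chromosomes after whole genome duplication. Deletion events
    excise a geometrically distributed number of contiguous genes from one
    homeolog, chosen with fractionation bias phi; collisions with previous
    deletions on the same homeolog are skipped while collisions with the
    other homeolog block the event, so that one copy of every gene always
    survives. The package provides a stochastic simulator of this process on
    long intervals, a deterministic recurrence for the distribution pi(r) of
    the number of deletion events composing each run of single-copy genes as
    the duplicate proportion theta decays, estimators of the mean deletion
    length mu and the bias phi from observable run statistics, and a
    validation harness comparing the recurrence with simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Genetics, Software, WholeGenome, MathematicalBiology
RoxygenNote: 7.3.3
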