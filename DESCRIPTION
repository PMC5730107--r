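Package: sleepsweep
Title: Evolve-and-Resequence Analysis of Artificial Selection on Drosophila Sleep
Version: 0.1.0
Authors@R: person("Sleepsweep", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing artificial-selection ("evolve and
    resequence") experiments on Drosophila sleep duration. Scores sleep
    phenotypes from activity-monitor minute counts, computes selection
    differentials and realized heritabilities, scans pooled allele-count
    tables for allele-frequency change with stratified Cochran-Mantel-
    Haenszel tests and a grouped logistic-regression filter, separates
    selection from drift with Wright-Fisher simulation and variance
    effective-size estimation, bounds linkage-disequilibrium persistence
    from pooled frequencies, and decomposes full diallel crosses into
    Griffing combining-ability effects. A synthetic-data generator with
    known ground truth supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
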