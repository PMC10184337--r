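Package: poemeth
Title: Phenome-Wide Analysis of the Parent-of-Origin-Effect Methylome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phenome-wide association analysis of
    parent-of-origin-effect (POE) CpG sites in array methylation data.
    Implements single-CpG association testing with a mixed linear model
    carrying an omic relationship matrix random effect, a fixed-effect
    CpG-outcome validation model, an FDR-controlled
    discovery/replication/validation workflow, rank-based enrichment of
    POE association signal against the rest of the methylome, weighted
    co-methylation module construction with recursive genomic pruning and
    cross-cohort module matching, module principal-component phenome
    scans, age-stratified within-module connectivity dynamics, methylation
    Shannon entropy and its drift with age, and a circular-permutation
    test of connectivity between POE CpGs and epigenetic-clock CpGs.
    Includes a synthetic cohort generator that reproduces the statistical
    structure the analyses assume, for end-to-end testing and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
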