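Package: SubsiteProfiler
Title: Peptidase Substrate-Specificity Profiling from P4-P4' Cleavage Windows
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing peptidase substrate specificity from
    literature-curated cleavage-site collections in the style of the MEROPS
    database. Parses and canonicalises MEROPS identifiers (protein-species,
    complexes, compound inhibitors, unsequenced peptidases, nonpeptidase
    homologs), constructs Schechter-Berger P4-P4' substrate windows, builds
    per-peptidase nonredundant cleavage sets, computes per-site residue
    frequency matrices, reports restricted, excluded and dominant binding
    sites, infers exopeptidase activity kinds from subsite occupancy, and
    detects co-operative binding between adjacent subsites. Includes a seeded
    synthetic cleavage-collection generator with planted specificity features
    so the whole pipeline is testable without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, Software, Preprocessing
RoxygenNote: 7.3.3
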