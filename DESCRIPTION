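Package: holoscreen
Title: Quality Control, Contamination Screening and Marker Discovery for
    Holobiont Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and cleaning de novo transcriptome
    assemblies from hosts that live in symbiosis (e.g. corals and sea
    anemones with their dinoflagellate symbionts). Implements whole-read
    quality/adapter/poly-A filtering, assembly size statistics with a
    core-set length cutoff, reference-gene representation and two Ortholog
    Hit Ratio completeness metrics, a decision tree assigning each
    transcript a taxonomic origin from tabular homology-search evidence, an
    abundance-ratio screen for cross-library contamination, gene-name
    transfer with uninformative-name exclusion and reciprocal-search gene
    lookup, imperfect microsatellite (SSR) discovery with primer-target
    selection, and taxon-occupancy-filtered phylogenomic supermatrix
    construction. A synthetic-data generator with planted truth makes every
    stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
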