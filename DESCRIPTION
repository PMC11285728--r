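Package: argfit
Title: Fitness Costs of Antibiotic Resistance Genes Across Host Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of competitive fitness effects of plasmid-borne
    antibiotic resistance genes (ARGs) from flow-cytometry competition
    counts, including start-frequency quality filtering, replicate
    aggregation with t-intervals, and resampling-based many-against-one
    testing of each ARG against the empty-vector control. Companion tools
    cover qPCR copy-number calculations (delta-delta-Ct), diagnostics for
    plasmid-loss and compensatory-mutation bias, phylogenetic-signal tests
    (Pagel's lambda and Blomberg's K) of per-strain ARG effects, a
    batch-culture growth model for baseline strain fitness, and an
    individual-based Wright-Fisher simulator of strain-by-ARG communities
    with persistence classification and strain/ARG dropout analysis. A
    synthetic-data generator reproduces the statistical structure of the
    assays so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
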