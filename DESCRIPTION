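Package: netdrift
Title: Neutral Cultural Drift on Interaction Networks of Subpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-time simulation of neutral cultural transmission in a
    haploid population of fixed size partitioned into subpopulations that
    interact over an explicit network. Individuals copy trait labels
    Wright-Fisher style from their own community or, with a small
    per-individual probability, from a network-neighbour community, with
    optional infinite-alleles innovation. Includes Watts-Strogatz small-world
    and spatial k-nearest-neighbour network builders, a seedable synthetic
    island point-pattern generator, the fixation index F_ST, trait richness,
    heterozygosity and rare-trait retention statistics, replicate aggregation
    with confidence bands, parameter-sweep orchestration with preset
    experiment families, and an exact Markov-chain oracle for validating the
    stochastic kernel on tiny instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
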