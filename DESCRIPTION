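Package: magiclink
Title: Evolution of Physical Linkage Between a Magic Trait and Mating-Preference Loci
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of a two-habitat
    population in which a single "magic trait" locus is under divergent
    ecological selection and simultaneously serves as the mating cue, while
    mating preferences are polygenic, built up by mutations scattered along
    the chromosome. The package tracks how physical linkage between the
    trait locus and preference loci evolves, and ships the full measurement
    layer: preference- and neutral-locus distance statistics, assortative
    mating (matching-pair) proportions, preference-position histograms,
    replicate and parameter-sweep orchestration, and the associated Pearson
    correlation and OLS F-test analyses. Includes a command-line interface
    for running single simulations and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
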