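Package: hetocs
Title: Genomic Optimal Contribution Selection with Heterozygote-Homozygote Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic optimal contribution selection (GOCS) in which
    the realized genomic relationship matrix is transformed to reward or
    penalize heterozygote-by-homozygote locus states between candidate pairs
    (G* = G + beta*Q).  Provides the unscaled -1/0/1 relationship matrices,
    a strictly convex quadratic program for optimal contributions under
    simplex and box constraints, linear-programming mate allocation that
    minimizes expected progeny homozygosity, gamete simulation with Poisson
    (Haldane) recombination along a genetic map, ridge-regression genomic
    evaluation on a cumulative reference population, a synthetic founder
    generator with controllable linkage disequilibrium and population
    structure, and a multigeneration breeding-program simulator with
    trajectory metrics and sequential (type I) analysis of variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    quadprog,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
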