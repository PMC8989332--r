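Package: dmiscan
Title: Detecting Dobzhansky-Muller Incompatibilities from Hybrid Genomes
    with the Variance in Two-Locus Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-locus statistics for detecting Dobzhansky-Muller
    incompatibilities (DMIs) in admixed populations from ancestry-call data.
    Implements the X(2) statistic (the normalized deviation of the variance
    in two-locus heterozygosity from its linkage-equilibrium expectation)
    and the recombinant-imbalance statistic Delta-D2, deterministic haploid
    and diploid two-locus DMI dynamics with recombination and migration, a
    forward-time individual-based Wright-Fisher and Moran simulator of
    admixed genomes, and a genome-scan pipeline with locus filtering, LD
    thinning, candidate calling, megabase binning and bootstrap support
    calibrated by a binomial test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
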