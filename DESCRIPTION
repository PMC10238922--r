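Package: bsamap
Title: Bulk Segregant Analysis QTL Mapping for Selfing Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pooled-sequencing bulk segregant analysis (BSA) for recombinant
    inbred line (RIL) crosses, as used to map a chromosome IV quantitative
    trait locus for neuron final position segregating between two
    Caenorhabditis elegans wild isolates. Starting from per-site allelic
    depths of two extreme-phenotype pools, the package computes pool allele
    frequencies, applies a sliding-window smoother, scans the genome with a
    pseudocounted log-odds-ratio statistic, calibrates a genome-wide
    significance threshold by Monte Carlo simulation of a binomial null, and
    calls candidate QTL intervals. A forward simulator of selfing RIL
    populations (Poisson crossovers, Haldane map function) and of pooled
    short-read counts makes every stage testable without external data, and
    the nonparametric statistics used for cross and introgression-line
    phenotype comparisons (Wilcoxon rank-sum, Kruskal-Wallis with Dunn's
    post hoc test and Bonferroni adjustment, compact letter display) are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
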