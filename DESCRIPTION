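Package: sighotspot
Title: Discovery of Somatic Mutation Hotspots Associated with Mutational
    Signature Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of somatic single-nucleotide-variant
    hotspots whose carriers show elevated (or depleted) exposure to a
    mutational signature.  The pipeline builds 96-class mutation catalogs
    (trinucleotide or NxSxN penta-reduced contexts), assigns signature
    exposures by non-negative least squares, scans the genome in
    half-overlapping 2 kb windows, prunes each window to hotspot
    sub-windows by a weighted mutational-load rule, tests hotspot genotype
    matrices against exposures with a covariate-adjusted SKAT-O-style
    kernel score test calibrated by residual resampling, and classifies
    significant hotspots as putative coding or non-coding drivers using
    chromatin-state, gene-model and known-driver annotation with
    permutation and hypergeometric enrichment tests.  A seeded synthetic
    tumor-cohort simulator provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    pracma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
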