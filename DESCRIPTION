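Package: phyloconflict
Title: Quantifying Conflicting Phylogenomic Signal Among Closely Spaced
    Divergences
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting conflicting phylogenomic signal among a
    small set of clades whose divergences fall within a few million years,
    as in the laurasiatherian orders Carnivora, Cetartiodactyla, Chiroptera
    and Perissodactyla.  Provides exhaustive rooted-topology enumeration and
    constrained maximum-likelihood evaluation under GTR/WAG with discrete
    gamma rate variation and invariant sites, a per-gene topology census
    with explicit tie and rejection rules, the Shimodaira-Hasegawa test with
    RELL resampling, threshold consensus split networks exported in
    SplitsTree format, an alignment-property influence analysis with
    chi-square tests, an in-silico retroposon (LINE1) presence/absence
    marker screen, nonparametric rate smoothing on a log scale for
    divergence dating, and a multispecies-coalescent synthetic-data
    generator (gene trees, sequence alignments, retroposon insertion loci)
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
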