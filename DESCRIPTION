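Package: ylineage
Title: Y-Chromosome Phylogeny Construction, Rho Dating, Haplogroup
    Calling and Phylogeographic Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for haploid (Y-chromosome) sequence
    analysis: hard-filtering of haploid genotype calls (SnpGap/indel
    removal, depth- and allele-balance-based genotype masking,
    sample- and site-level missingness cuts), perfect-phylogeny tree
    construction from binary SNV matrices with a parsimony fallback and
    midpoint rooting, rho-statistic dating of internal nodes from
    cross-clade pairwise divergences with mutation-rate-propagated
    confidence intervals, lineage-through-time counting, haplogroup
    assignment by greedy descent of a marker tree, and inverse-distance
    (generalized Shepard) interpolation of haplogroup frequencies into
    presence and combination maps. A seeded coalescent simulator with
    infinite-sites mutations, sequencing artifacts, planted haplogroup
    markers and geolocated populations provides ground-truthed inputs
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    phytools,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
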