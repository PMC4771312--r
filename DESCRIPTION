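Package: MetalTraits
Title: Comparative Genomics of Trace-Metal Uptake Gene Inventories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing trace-metal (Fe, Mn, Zn, Co, Ni, Cu)
    uptake gene inventories in bacterial genome collections such as the
    marine SAR11 and Roseobacter lineages. Builds genome-by-family
    transporter inventories from filtered domain-model hits, scans upstream
    regions for Fur-box-like palindromes and 7-1-7 inverted repeats, tests
    gene-neighborhood enrichment around TonB-dependent transporters with
    Fisher's exact test and classifies siderophore/heme uptake loci by
    colocalization rules, clusters protein similarity graphs with a
    from-scratch Markov clustering (MCL) implementation, quantifies
    phylogenetic trait conservation with consenTRAIT trait depth and the
    Fritz-Purvis dispersion statistic D, and provides a multivariate layer
    (Bray-Curtis, PCA, permutation vector fitting, dispersion and
    correlation screens). A synthetic-data module generates trees with
    clumped, random or Brownian-threshold binary traits, genomes with
    planted transporter loci and regulatory motifs, planted-partition
    similarity graphs and two-lineage count matrices, so the whole pipeline
    is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
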