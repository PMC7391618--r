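Package: herddiv
Title: Haplotype-Block Diversity and Population Structure for Livestock SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide diversity and population-structure analysis of
    SNP-array genotypes organised in short haplotype blocks, as used in
    conservation genetics of local livestock breeds. Implements marker and
    sample quality control, a unified additive relationship (UAR) matrix with
    per-animal inbreeding and relatedness pruning, 4-SNP haplotype blocks
    treated as multi-allelic markers, allelic-diversity statistics (allelic
    richness by rarefaction, private and semi-private alleles, unbiased
    heterozygosity), Jost's D differentiation, allele-sharing distances with
    classical multidimensional scaling, Nei's D_A distances with
    neighbor-joining trees, linkage-disequilibrium based historical effective
    population size, Patterson's D (ABBA-BABA) with weighted block-jackknife
    standard errors, and truth-known synthetic-data generators for all of the
    above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    phytools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
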