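# herddiv

Genomic diversity and population-structure analysis for multi-breed
livestock SNP panels, built around short haplotype blocks treated as
multi-allelic markers.

## Who this is for

Conservation geneticists and animal-breeding researchers working with
SNP-array genotypes of many small local breeds. Arrays are ascertained on a
handful of cosmopolitan breeds, so single-SNP diversity statistics are
biased against exactly the populations conservation cares about. `herddiv`
collapses runs of 4 consecutive SNPs (span < 150 kb, adjacent gaps < 50 kb)
into multi-allelic block markers whose alleles are the observed haplotype
words, and computes the classical multi-allelic statistics on them.

## What it computes

* **QC**: sample/SNP call-rate filters, pooled MAF filter, exact
  within-breed Hardy–Weinberg test (probability-ordering, enumeration-exact).
* **Relationships**: the unified additive relationship (UAR) matrix
  `UAR[i,j] = mean_k (x_ik − 2p_k)(x_jk − 2p_k) / (2 p_k (1 − p_k))`, genomic
  inbreeding `F_i = UAR[i,i] − 1`, robust multivariate outlier flags, greedy
  relatedness pruning.
* **Diversity per breed**: allele counts (nA, mA), observed and unbiased
  expected heterozygosity, heterozygote deficit, allelic richness by
  rarefaction `AR_g = Σ_u [1 − C(N−N_u, g)/C(N, g)]`, private/semi-private/
  common alleles and private-allele frequency; Nd-weighted group summaries;
  correlations of F with private-allele statistics.
* **Differentiation**: Jost's D for multi-allelic markers with small-sample
  corrections; Bowcock allele-sharing distances; classical MDS with breed
  centers and SD dispersion radii.
* **Phylogeny**: Nei's `D_A = 1 − (1/L) Σ_l Σ_u √(x_lu y_lu)`, an exact
  Saitou–Nei neighbor-joining implementation, outgroup rooting, Newick
  export.
* **Historical Ne**: LD decay with distance,
  `Ne(t) = (4c)^-1 (E[r²_adj]^-1 − α)` at `t = 1/(2c)`, with sample-size and
  recombination-rate corrections; per-breed Ne at 5, 50 and 2000
  generations.
* **Introgression**: Patterson's D (ABBA-BABA) from population frequencies
  with weighted block-jackknife Z scores (|Z| > 3 significant).
* **Simulators**: Balding–Nichols hierarchical cohorts, a forward
  Wright–Fisher simulator with recombination, and a four-population drift
  graph — every estimator has a truth-known test substrate.

A transcribed 115-breed reference table of published per-breed statistics
ships with the package (`load_reference_table()`) and anchors the group
summaries and correlations end to end.

## Worked example

```r
library(herddiv)

# three-breed cohort: a large outbred breed, a drifted one, and a small
# inbred island breed
sim <- simulate_hierarchical(
  n_pops = 3, n_per_pop = c(20, 12, 8), n_snps = 2000,
  fst = c(0.05, 0.10, 0.20), inbreeding = c(0, 0.05, 0.25),
  groups = c("mainland", "mainland", "island"), seed = 11)

tab <- summarize_breeds(sim$haplotypes, sim$breeds)
print(tab[, c("breed", "Nd", "mA", "H_O", "H_E", "npA", "fpA", "AR", "F")],
      digits = 3)
#>   breed Nd   mA   H_O   H_E  npA    fpA   AR      F
#> 1 POP01 20 9.98 0.821 0.824 1297 0.0481 7.07 0.0151
#> 2 POP02 12 7.65 0.780 0.796  502 0.0667 6.51 0.0972
#> 3 POP03  8 5.72 0.628 0.740  299 0.0959 5.72 0.3214
```

The inbred island breed (truth F = 0.25, strongest drift) shows exactly the
expected syndrome: lowest heterozygosity and allelic richness, fewer but
higher-frequency private alleles, and an inbreeding estimate near its truth.
Group summaries weight breeds by their retained sample sizes:

```r
group_weighted_summary(tab, sim$breeds, stats = c("H_E", "AR", "F"))
#>      group Nd_total n_breeds   H_E   AR      F
#> 1 mainland       32        2 0.813 6.86 0.0459
#> 2   island        8        1 0.740 5.72 0.3214
```

Differentiation and a neighbor-joining tree from the same block alleles:

```r
blocks <- build_blocks(sim$haplotypes$map)
bg     <- encode_block_alleles(sim$haplotypes, blocks)
counts <- breed_allele_counts(bg, sim$breeds)
round(unclass(dest_matrix(counts)), 3)
#>       POP01 POP02 POP03
#> POP01 0.000 0.142 0.276
#> POP02 0.142 0.000 0.311
#> POP03 0.276 0.311 0.000

tree <- neighbor_joining(nei_da_matrix(counts))
ape::write.tree(tree)
#> [1] "(POP01:0.0841116856,POP02:0.1285851476,POP03:0.2242937979);"
```

The most drifted, inbred breed is the most differentiated (largest Jost's D
to both neighbours, longest branch), mirroring the published pattern for
isolated island cattle.

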