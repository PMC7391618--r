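---
title: "Haplotype-block diversity and population structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block diversity and population structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herddiv)
```

## The problem

Conservation genetics of local livestock breeds asks how much neutral
diversity a breed retains, how inbred and how differentiated it is, and
where its ancestry comes from. SNP-array panels answer these questions
cheaply, but arrays are designed from a small discovery panel of
cosmopolitan breeds, so single-SNP statistics are distorted by
ascertainment bias: rare and population-specific variation is
under-represented. `herddiv` follows the block-based strategy used in
multi-breed cattle studies: runs of a few tightly linked SNPs are collapsed
into one *multi-allelic* marker whose alleles are the observed haplotype
words. Rare haplotype combinations recover part of the variation the array
never typed directly, and classical multi-allelic statistics (allelic
richness, private alleles, Jost's D, Nei's D_A) become applicable.

The pipeline is: quality control → relationship matrix, inbreeding and
pruning → haplotype blocks → diversity and differentiation statistics →
phylogeny and MDS → LD-based historical effective population size →
ABBA-BABA introgression tests. Every stage has a truth-known synthetic
generator so the whole chain is testable without access rights to any real
cohort.

## Quality control

Four filters in a fixed order, with the conventional thresholds for
array data: individuals with call rate ≤ 0.95 are dropped; SNPs typed in
less than 90% of samples are dropped; SNPs with pooled minor allele
frequency below 0.025 are dropped; and SNPs out of Hardy–Weinberg
equilibrium *within a breed* (exact test, p ≤ 0.01) are dropped. Two
choices deserve comment:

* **HWE is tested per breed, with a minimum breed size** (default 10).
  Multi-breed panels are strongly Wahlund-structured, so a pooled test
  would discard perfectly good markers; and in breeds of 4–8 animals the
  test has essentially no power, so tiny breeds are never allowed to
  trigger removal. A SNP failing in *any* sufficiently large breed is
  removed — the conservative reading when genotyping artefacts are the
  target.
* **The test is exact and two-sided** by probability ordering (all
  heterozygote counts compatible with the allele counts are enumerated and
  those no more probable than the observation are summed). Chi-square
  approximations are unusable at these sample sizes; the implementation is
  verified against full enumeration for every configuration with up to 20
  individuals.

Re-running QC on its own output removes nothing, which the suite asserts.

## Relationships, inbreeding and pruning

Genome-wide additive relationships use the unified additive relationship
(UAR) form: for SNP dosages $x_{ik}$ and cohort frequencies $p_k$,

$$\mathrm{UAR}_{ij} = \frac{1}{m}\sum_k
  \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)}, \qquad
\mathrm{UAR}_{ii} = 1 + \frac{1}{m}\sum_k
  \frac{x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2}{2p_k(1-p_k)},$$

so the genomic inbreeding coefficient is $F_i = \mathrm{UAR}_{ii}-1$.
Frequencies are computed once on the full post-QC cohort, not per breed: a
single genome-wide matrix is what drives both outlier detection and
relatedness pruning, and per-breed centring would make relationships
incomparable across breeds.

Outlier animals (mislabelled samples, strongly admixed individuals) are
flagged per breed: the within-breed UAR sub-matrix is embedded by principal
coordinates (top 5 axes by default), each axis is standardised robustly by
median and MAD (falling back to the standard deviation on degenerate axes,
e.g. near-clonal breeds), and the squared distance is compared with the
upper 2.5% chi-square quantile. Breeds under 5 animals are skipped — a
robust covariance cannot be estimated there, and in this regime a curator
should look at the animals individually anyway.

Relatedness pruning is greedy: while any within-breed pair exceeds the
threshold (default 0.45, roughly first-degree relatives), the individual
with the most above-threshold partners is removed; ties fall to the larger
mean relationship, then to the smaller identifier, so the output is
deterministic. Removing the most-connected animal first minimises removals
on star-shaped family structures (one sire, many offspring), which is the
typical shape in small breeds with few breeding males. The post-condition —
no surviving within-breed pair above the threshold — is asserted in the
tests.

## Haplotype blocks

Blocks are built per chromosome by a greedy left-to-right scan: the next 4
unconsumed consecutive SNPs form a block if the block spans **less than
150 kb** and every adjacent gap is **shorter than 50 kb** (both strict); on
success all 4 SNPs are consumed, otherwise the window slides one SNP. The
scan is deterministic, blocks never overlap or cross chromosomes, and on a
uniformly spaced dense map the block count is exactly ⌊SNPs/4⌋. A `jump`
variant (restart past a failing window) is available behind an argument;
slide-by-one is the default because it forms more blocks on irregular maps.
Each individual then carries two 4-symbol words per block; the word pairs
are the multi-allelic genotypes all downstream statistics consume.

## Diversity statistics

Per breed: the total (`nA`) and mean (`mA = nA/n_blocks`) number of block
alleles; observed heterozygosity `H_O` (fraction of heterozygous block
genotypes, averaged over blocks); unbiased expected heterozygosity
`H_E` with Nei's small-sample factor $\frac{2N}{2N-1}(1-\sum_u p_u^2)$ —
essential with breeds as small as 4 animals; the heterozygote deficit
`H_def = (H_E − H_O)/H_E`; allelic richness by hypergeometric rarefaction

$$AR_g = \sum_u \left[1 -
  \binom{N-N_u}{g}\Big/\binom{N}{g}\right]$$

averaged over blocks, at a common depth `g` defaulting to twice the
smallest breed size so every breed supports the subsample; and private
(`npA`, breed-occupancy 1), semi-private (`nspA`, occupancy 2, credited to
both carriers) and common (`ncA`, occupancy = all breeds) alleles, with
`fpA` the mean within-breed frequency of a breed's private alleles. SNP-based
heterozygosities are reported alongside the block-based ones precisely to
expose the ascertainment gap between the two.

Group-level values are **Nd-weighted means** over the group's breeds
(weights = retained animals per breed), with breeds lacking a statistic
excluded from that statistic's weighting only. This weighting reproduces
the packaged reference table's printed group rows, which is how it was
selected among the plausible conventions. Ne estimates are reported only
for breeds with at least 8 retained animals, mirroring the reference
table's empty cells.

The correlations of inbreeding with private-allele statistics
(`correlate_f_private()`) are computed over domesticated breeds, excluding
divergent outgroups: an outgroup's enormous private-allele load and
off-scale inbreeding coefficient (measured against cohort frequencies it
barely shares) would otherwise dominate both correlations. On the packaged
table this choice reproduces the published values (r(F, fpA) = 0.72,
r(F, npA) = −0.21); including the outgroups moves r(F, npA) to ≈ 0.

## Differentiation

Jost's D is used instead of G_ST-type indices because block markers are
highly polymorphic within breeds, exactly the regime where G_ST saturates.
For two breeds with harmonic-mean size $\tilde N$:
$\hat H_S$ is the sample-corrected mean within-breed gene diversity,
$\hat H_T = 1-\sum_u \bar p_u^2 + \hat H_S/(4\tilde N)$, and
$D = 2\,(\hat H_T-\hat H_S)/(1-\hat H_S)$. Across blocks the components
$\hat H_S$, $\hat H_T$ are averaged before forming D (the stabler
aggregation when many blocks are near-monomorphic); averaging per-block D
values is available via `aggregate = "per_locus_mean"`. Slightly negative
finite-sample estimates are clamped to zero.

Between individuals, the allele-sharing distance at one block is
$1 - \text{(shared alleles)}/2$ where shared ∈ {0, 1, 2} is the multiset
intersection of the two genotype pairs; `D_PS` averages over blocks.
Classical MDS (principal coordinates via `stats::cmdscale`) projects the
D_PS matrix to the plane; coordinates are defined only up to
rotation/reflection, so a fixed sign convention (largest-magnitude loading
positive) makes runs reproducible. Breed symbols are drawn at the member
mean with a radius equal to the standard deviation of member–center
Euclidean distances.

## Phylogeny

Nei's D_A, $1-\frac{1}{L}\sum_l\sum_u\sqrt{x_{lu}y_{lu}}$, is computed from
block allele frequencies without a small-sample correction (the corrected
variant of the distance is not uniquely specified in the literature the
package follows; the uncorrected form is the common default). Trees are
built with an in-package Saitou–Nei neighbor-joining implementation:
deterministic lexicographic tie-breaking on the Q-criterion, negative
branch lengths clamped to zero with the deficit moved to the sister edge.
On additive matrices the original tree is recovered exactly (property-tested
against random trees up to 8 taxa, and cross-checked against `ape::nj`).
Rooting places the root at the midpoint of the outgroup's pendant edge,
leaving all leaf-to-leaf path lengths unchanged; trees export as Newick.

## LD-based historical Ne

For one breed's phased haplotypes, r² is the squared correlation of allele
indicators for all intra-chromosomal pairs between 20 kb and 10 Mb. Sites
below 5% within-breed MAF are excluded — near-fixed sites can only carry
tiny r² values and would bias the decay curve downward. Physical distance
maps to recombination fraction linearly at 1 cM/Mb by default (a Haldane
map is selectable); pairs are grouped into 30 log-spaced distance bins,
matching the hyperbolic r²–c relation, and each bin yields

$$\hat N_e(t) = \frac{1}{4c}\left(\frac{1}{E[r^2_{adj}]}-\alpha\right),
\qquad t = \frac{1}{2c},$$

with the bin's harmonic-mean c, the sample-size correction
$r^2_{adj} = r^2 - 1/(\beta n)$ (β = 2 for phased input, i.e. one over the
number of haplotypes) and α = 2 (mutation ignored; 2.2 selectable).
`Ne_5`, `Ne_50`, `Ne_2000` are read from the bins whose t is nearest 5, 50
and 2000 generations. Bins whose adjusted mean r² is non-positive (or
implies a non-positive Ne) are reported as undefined rather than clamped —
at small c the −α term legitimately dominates noisy bins.

The recovery test runs a forward Wright–Fisher population of constant size
100 for 400 generations with 500 sites on a 50 Mb chromosome and requires
the median recent-time estimate over 50 replicates to fall within ±30% of
the truth. These problem sizes keep a single replicate around two seconds
while leaving the recent-time bins well populated.

## ABBA-BABA

Patterson's D uses the population-frequency form with an **ABBA-positive**
sign convention,

$$D = \frac{\sum_k (p_{2k}-p_{1k})(p_{3k}-p_{Ok})}
           {\sum_k (p_{1k}+p_{2k}-2p_{1k}p_{2k})(p_{3k}+p_{Ok}-2p_{3k}p_{Ok})},$$

which reduces to the normalised ABBA−BABA pattern count at fixed sites:
D > 0 means excess P2–P3 sharing, D < 0 excess P1–P3 sharing, and the
ancestral state is polarised implicitly by the outgroup term, so no
external ancestral-state file is needed. Standard errors come from a
weighted delete-one block jackknife (Busing's formulas) over 5 Mb genomic
windows — comfortably beyond cattle LD range and configurable — with
weights proportional to per-window informative-site counts; |Z| > 3 flags
significance, two-sided, so a scan that tests candidate introgressed
breeds as P1 against a clean P2 flags them through negative D exactly as
the ABBA-oriented simulations flag positive D.

## Synthetic data: what it does and does not emulate

Three generators provide truth-known substrates, all deterministic in a
single seed:

* `simulate_hierarchical()` — Balding–Nichols drift: ancestral frequencies
  Uniform(0.05, 0.95) (mimicking array ascertainment against rare
  variants), per-population Beta-drifted frequencies with divergence
  parameter F_ST, optional admixture mixing of source frequencies, and
  within-individual allele correlation equal to the inbreeding parameter.
  Sites are exchangeable — there is **no LD** beyond inbreeding — so this
  generator exercises frequency-based statistics (diversity, D_EST, D_A,
  UAR, outliers) but cannot test LD machinery.
* `simulate_wright_fisher()` — a discrete-generation forward simulator with
  Poisson recombination on one chromosome, supplying realistic LD decay for
  the Ne estimator and for haplotype-block structure.
* `simulate_dstat_graph()` — frequency evolution along (((P1,P2),P3),O)
  with per-branch drift and optional P3→P2 introgression, the null and
  power substrate for the D statistic.

None of the generators emulates genotyping error, array-specific marker
spacing, phasing errors (haplotypes are known by construction, whereas real
phased data carry switch errors that deflate long-range r²), or selection.
Passing recovery tests therefore demonstrates that the estimators are
correct on their stated models, not that the biological conclusions of any
particular cohort are robust to those nuisances.

## Numerical and design choices

* Dosages are centred and scaled per SNP before the UAR cross-product;
  residual missing dosages are mean-imputed (equivalent to contributing
  zero) and counted.
* The exact HWE p-value sums probabilities with a 1e-12 slack on the
  comparison so ties of equal-probability configurations are included
  regardless of floating-point noise.
* PED input carries no ref/alt designation; the alternate allele is the
  lexicographically larger observed allele — arbitrary, but deterministic
  and documented, and irrelevant to every downstream statistic (which are
  allele-label invariant; the suite asserts this for D_EST).
* The packaged 115-breed reference table ships with an MD5 checksum; the
  loader refuses a corrupted file. Its per-breed rows satisfy the internal
  identities mA = nA/5756 and H_def = (H_E−H_O)/H_E to printed precision,
  and its Nd-weighted group means reproduce the printed group rows.
* Problem sizes in the test suite (tens of individuals, hundreds to a few
  thousand markers, 25–50 simulation replicates) were chosen so the whole
  suite runs in a few minutes on one core while keeping every stochastic
  band at least three standard errors wide.

## Known limitations

* The greedy block tiling is one of several defensible tilings; block
  counts on irregular maps depend on the slide/jump choice (both shipped).
* Jost's D aggregation across loci is not standardised in the field; both
  shipped variants can differ noticeably when many blocks are
  near-monomorphic.
* The linear 1 cM/Mb genetic map ignores regional recombination-rate
  variation; chromosome-specific maps are out of scope.
* The Ne curve inherits all known biases of LD-based estimators at very
  recent and very ancient times (few informative pairs at the extremes of
  the distance range).
* Correlations and group summaries computed from the packaged reference
  table inherit that table's printed rounding.
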