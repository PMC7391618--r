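#' Per-breed diversity summary from phased haplotypes
#'
#' Convenience pipeline for an already QC'd, pruned cohort: builds the
#' haplotype blocks, encodes block genotypes, tallies breed allele counts
#' and assembles the standard per-breed row (Nd, nA, mA, H_O, H_E, H_def,
#' npA, nspA, fpA, AR, F, SNP heterozygosities). The UAR used for F is
#' centred on the full cohort's frequencies.
#'
#' @param h a `haplotype_matrix` for the cohort.
#' @param breeds a `breed_assignment`.
#' @param block_size,max_span,max_gap block construction parameters, see
#'   [build_blocks()].
#' @param rarefaction_g rarefaction depth; default `2 * min(Nd)`.
#' @return `data.frame` with one row per breed; the `block_allele_table`
#'   is attached as attribute `table`.
#' @export
summarize_breeds <- function(h, breeds, block_size = 4L, max_span = 150000L,
                             max_gap = 50000L, rarefaction_g = NULL) {
  stopifnot(inherits(h, "haplotype_matrix"))
  blocks <- build_blocks(h$map, block_size, max_span, max_gap)
  if (nrow(blocks) == 0L) stop("summarize_breeds: map admits no blocks")
  bg <- encode_block_alleles(h, blocks)
  tab <- breed_allele_counts(bg, breeds)
  div <- diversity_summary(tab)
  ar <- allelic_richness(tab, rarefaction_g)
  pv <- private_allele_counts(tab)
  g <- as_genotypes(h)
  # UAR needs cohort-polymorphic SNPs; fixed sites carry no information
  p_all <- colMeans(g$dosage) / 2
  poly <- p_all > 0 & p_all < 1
  g_uar <- subset_genotypes(g, keep_snp = poly)
  uar <- uar_matrix(g_uar)
  Fi <- inbreeding_from_uar(uar)
  br <- breed_of(breeds, g$ids)
  Fb <- tapply(Fi, br, mean)
  snp <- snp_heterozygosity(g, breeds)
  out <- merge(div, snp, by = "breed", sort = TRUE)
  out$npA <- as.integer(pv$npA[out$breed])
  out$nspA <- as.integer(pv$nspA[out$breed])
  out$fpA <- pv$fpA[out$breed]
  out$AR <- ar[out$breed]
  out$F <- as.numeric(Fb[out$breed])
  attr(out, "table") <- tab
  attr(out, "ncA") <- pv$ncA
  attr(out, "n_alleles_total") <- pv$n_alleles_total
  out
}
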