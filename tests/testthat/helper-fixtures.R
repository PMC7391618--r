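# Small builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# haplotype matrix from an explicit allele matrix on a uniform 10 kb map
toy_haplotypes <- function(alleles, chrom = NULL, spacing = 10000L, ids = NULL) {
  alleles <- as.matrix(alleles)
  m <- ncol(alleles)
  if (is.null(chrom)) chrom <- rep("1", m)
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * spacing
  map <- marker_map(paste0("s", seq_len(m)), chrom, pos)
  haplotype_matrix(alleles, map, ids)
}

toy_genotypes <- function(dosage, chrom = NULL, spacing = 10000L, ids = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * spacing
  map <- marker_map(paste0("s", seq_len(m)), chrom, pos)
  genotype_matrix(dosage, map, ids)
}

one_breed <- function(ids, breed = "B1", group = "G1") {
  breed_assignment(ids, rep(breed, length(ids)), rep(group, length(ids)))
}

# block-allele table straight from per-breed count matrices:
# counts_list: list over blocks of matrices (alleles x breeds), all sharing
# breed columns; copies derived from the first block's column sums.
manual_allele_table <- function(counts_list, het = NULL, n_ind = NULL) {
  breeds <- colnames(counts_list[[1]])
  copies <- colSums(counts_list[[1]])
  if (is.null(n_ind)) n_ind <- copies / 2
  if (is.null(het)) het <- matrix(0L, length(counts_list), length(breeds),
                                  dimnames = list(NULL, breeds))
  structure(list(counts = counts_list, het = het,
                 n_ind = stats::setNames(as.integer(n_ind), breeds),
                 copies = stats::setNames(as.integer(copies), breeds),
                 breeds = breeds),
            class = "block_allele_table")
}

# genotype cohort sampled from four population frequency vectors, for
# D-statistic scans (breeds O, P3, P2 and one or more P1s)
dstat_cohort <- function(freqs, n_per_pop = 20L, seed = 1L) {
  set.seed(seed)
  pops <- names(freqs)
  m <- length(freqs[[1]])
  dosage <- NULL; ids <- character(0); breed <- character(0)
  for (b in pops) {
    d <- matrix(stats::rbinom(n_per_pop * m, 2L, rep(freqs[[b]], each = n_per_pop)),
                nrow = n_per_pop)
    dosage <- rbind(dosage, d)
    ids <- c(ids, sprintf("%s_%02d", b, seq_len(n_per_pop)))
    breed <- c(breed, rep(b, n_per_pop))
  }
  map <- marker_map(paste0("m", seq_len(m)), "1", seq_len(m) * 50000L)
  list(genotypes = genotype_matrix(dosage, map, ids),
       breeds = breed_assignment(ids, breed, breed))
}
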