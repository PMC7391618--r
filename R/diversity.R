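#' Per-breed block-allele counts
#'
#' Tallies, for every breed and every block, how many gene copies carry
#' each block allele (word). Heterozygote counts per breed and block are
#' recorded alongside so that observed heterozygosity can be computed from
#' the same object.
#'
#' @param bg `block_genotypes` from [encode_block_alleles()].
#' @param breeds a `breed_assignment`; every individual must be assigned.
#' @return Object of class `block_allele_table` with elements `counts`
#'   (list, one allele-by-breed count matrix per block), `het` (block x
#'   breed heterozygote counts), `n_ind` (named breed sizes Nd) and
#'   `copies` (2 * Nd).
#' @export
breed_allele_counts <- function(bg, breeds) {
  stopifnot(inherits(bg, "block_genotypes"))
  br <- breed_of(breeds, bg$ids)
  breed_levels <- sort(unique(br))
  if (any(table(br) == 0L)) stop("breed_allele_counts: empty breed")
  nb <- ncol(bg$a1)
  brf <- factor(br, levels = breed_levels)
  counts <- vector("list", nb)
  het <- matrix(0L, nb, length(breed_levels),
                dimnames = list(colnames(bg$a1), breed_levels))
  for (j in seq_len(nb)) {
    w <- c(bg$a1[, j], bg$a2[, j])
    f <- factor(c(br, br), levels = breed_levels)
    counts[[j]] <- unclass(table(w, f))
    het[j, ] <- tabulate(brf[bg$a1[, j] != bg$a2[, j]],
                         nbins = length(breed_levels))
  }
  names(counts) <- colnames(bg$a1)
  n_ind <- stats::setNames(as.integer(table(brf)), breed_levels)
  structure(list(counts = counts, het = het, n_ind = n_ind,
                 copies = 2L * n_ind, breeds = breed_levels),
            class = "block_allele_table")
}

#' Per-breed allelic and heterozygosity summary
#'
#' For each breed: total observed alleles over blocks (`nA`), mean alleles
#' per block (`mA = nA / n_blocks`), observed heterozygosity (`H_O`, mean
#' over blocks of the heterozygous-individual fraction), unbiased expected
#' heterozygosity (`H_E`, mean over blocks of
#' \eqn{\frac{2N}{2N-1}(1 - \sum_u p_u^2)} with `N` the breed size) and the
#' heterozygote deficit `H_def = (H_E - H_O) / H_E`.
#'
#' @param t a `block_allele_table`.
#' @return `data.frame` with one row per breed.
#' @export
diversity_summary <- function(t) {
  stopifnot(inherits(t, "block_allele_table"))
  nb <- length(t$counts)
  if (nb == 0L) stop("diversity_summary: empty table")
  breeds <- t$breeds
  nA <- he <- stats::setNames(numeric(length(breeds)), breeds)
  for (j in seq_len(nb)) {
    cm <- t$counts[[j]]
    nA <- nA + colSums(cm > 0L)
    p2 <- colSums((sweep(cm, 2L, t$copies[colnames(cm)], "/"))^2)
    Nc <- t$copies[colnames(cm)]
    he <- he + (Nc / (Nc - 1L)) * (1 - p2)
  }
  H_E <- he / nb
  H_O <- colMeans(sweep(t$het, 2L, t$n_ind[colnames(t$het)], "/"))
  data.frame(breed = breeds, Nd = as.integer(t$n_ind[breeds]),
             nA = as.integer(nA[breeds]), mA = nA[breeds] / nb,
             H_O = H_O[breeds], H_E = H_E[breeds],
             H_def = (H_E[breeds] - H_O[breeds]) / H_E[breeds],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct block alleles in a random subsample of `g`
#' gene copies, per breed, averaged over blocks:
#' \deqn{AR_g = \sum_u \left[1 - \binom{N - N_u}{g} / \binom{N}{g}\right]}
#' with `N` the copies sampled in the breed and `N_u` the copies of allele
#' `u`. Correcting to a common `g` makes allele counts comparable across
#' unequal breed sizes.
#'
#' @param t a `block_allele_table`.
#' @param g rarefaction depth in gene copies; defaults to `2 * min(Nd)`.
#' @return Named numeric vector of per-breed AR.
#' @export
allelic_richness <- function(t, g = NULL) {
  stopifnot(inherits(t, "block_allele_table"))
  if (is.null(g)) g <- min(t$copies)
  if (g > min(t$copies))
    stop("allelic_richness: g exceeds the smallest breed's gene copies")
  ar <- stats::setNames(numeric(length(t$breeds)), t$breeds)
  for (j in seq_along(t$counts)) {
    cm <- t$counts[[j]]
    for (b in colnames(cm)) {
      N <- t$copies[[b]]
      Nu <- cm[, b]; Nu <- Nu[Nu > 0L]
      ar[b] <- ar[b] + sum(1 - exp(lchoose(N - Nu, g) - lchoose(N, g)))
    }
  }
  ar / length(t$counts)
}

#' Private, semi-private and common alleles
#'
#' Allele identity is the pair (block, word). An allele observed in exactly
#' one breed is private (`npA`), in exactly two breeds semi-private
#' (`nspA`, credited to both carriers), and in all breeds common (`ncA`).
#' `fpA` is the mean within-breed frequency of that breed's private
#' alleles (`NA` when a breed has none).
#'
#' @param t a `block_allele_table` with at least two breeds.
#' @return List with per-breed vectors `npA`, `nspA`, `fpA`, scalar `ncA`
#'   and `n_alleles_total` (distinct alleles over all breeds).
#' @export
private_allele_counts <- function(t) {
  stopifnot(inherits(t, "block_allele_table"))
  breeds <- t$breeds
  if (length(breeds) < 2L) stop("private_allele_counts: need >= 2 breeds")
  npA <- nspA <- stats::setNames(integer(length(breeds)), breeds)
  fp_sum <- stats::setNames(numeric(length(breeds)), breeds)
  ncA <- 0L; total <- 0L
  for (j in seq_along(t$counts)) {
    cm <- t$counts[[j]]
    present <- cm > 0L
    occ <- rowSums(present)
    total <- total + nrow(cm)
    ncA <- ncA + sum(occ == length(breeds))
    pv <- which(occ == 1L)
    for (u in pv) {
      b <- colnames(cm)[present[u, ]]
      npA[b] <- npA[b] + 1L
      fp_sum[b] <- fp_sum[b] + cm[u, b] / t$copies[[b]]
    }
    sv <- which(occ == 2L)
    for (u in sv) {
      bs <- colnames(cm)[present[u, ]]
      nspA[bs] <- nspA[bs] + 1L
    }
  }
  fpA <- ifelse(npA > 0L, fp_sum / npA, NA_real_)
  list(npA = npA, nspA = nspA, fpA = fpA, ncA = ncA, n_alleles_total = total)
}

#' SNP-based heterozygosities per breed
#'
#' The block estimators applied to single bi-allelic SNPs: per breed,
#' `H_O(SNP)` is the mean heterozygote fraction over SNPs and `H_E(SNP)`
#' the mean unbiased gene diversity. Reported alongside the block-based
#' values to expose array ascertainment bias.
#'
#' @param g a `genotype_matrix` (post-QC; missing genotypes are excluded
#'   per SNP).
#' @param breeds a `breed_assignment`.
#' @return `data.frame` with per-breed `H_O_snp`, `H_E_snp`.
#' @export
snp_heterozygosity <- function(g, breeds) {
  stopifnot(inherits(g, "genotype_matrix"))
  br <- breed_of(breeds, g$ids)
  out <- lapply(sort(unique(br)), function(b) {
    d <- g$dosage[br == b, , drop = FALSE]
    nonmiss <- colSums(!is.na(d))
    use <- nonmiss > 1L
    ho <- colMeans(d[, use, drop = FALSE] == 1, na.rm = TRUE)
    p <- colMeans(d[, use, drop = FALSE], na.rm = TRUE) / 2
    N <- nonmiss[use]
    he <- (2 * N / (2 * N - 1)) * (1 - p^2 - (1 - p)^2)
    data.frame(breed = b, H_O_snp = mean(ho), H_E_snp = mean(he),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Nd-weighted group summaries
#'
#' For each geographic group and each statistic, the Nd-weighted mean over
#' the group's breeds; breeds lacking a statistic (e.g. Ne for small Nd)
#' are dropped from that statistic's weighting only.
#'
#' @param table `data.frame` with columns `breed`, `Nd` and the statistics
#'   to summarise.
#' @param breeds a `breed_assignment` mapping breed codes to groups (one
#'   row per breed suffices, as from [reference_breed_groups()]).
#' @param stats character vector of columns to summarise; defaults to all
#'   numeric columns except `Nd`.
#' @return `data.frame` with one row per group.
#' @export
group_weighted_summary <- function(table, breeds, stats = NULL) {
  stopifnot(is.data.frame(table), "Nd" %in% names(table))
  grp <- breeds$group[match(table$breed, breeds$breed)]
  if (anyNA(grp)) stop("group_weighted_summary: breed without group")
  if (is.null(stats))
    stats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "Nd")
  out <- lapply(unique(grp), function(g) {
    rows <- table[grp == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("group_weighted_summary: empty group ", g)
    vals <- vapply(stats, function(s) {
      v <- rows[[s]]; w <- rows$Nd
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      sum(w[ok] * v[ok]) / sum(w[ok])
    }, numeric(1))
    cbind(data.frame(group = g, Nd_total = sum(rows$Nd), n_breeds = nrow(rows),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, out)
}

#' Correlation of inbreeding with private-allele statistics
#'
#' Pearson correlations of the per-breed inbreeding coefficient with the
#' frequency (`fpA`) and the number (`npA`) of private alleles. Fragmented
#' breeds under strong drift keep few but high-frequency private alleles,
#' so r(F, fpA) is expected positive and r(F, npA) weakly negative.
#' Divergent outgroups distort both; they can be excluded via
#' `exclude_groups` (requires a `group` column).
#'
#' @param table `data.frame` with columns `F`, `fpA`, `npA` (and `group`
#'   when `exclude_groups` is used).
#' @param exclude_groups optional character vector of groups to drop.
#' @return Named vector with `r_F_fpA` and `r_F_npA`.
#' @export
correlate_f_private <- function(table, exclude_groups = NULL) {
  stopifnot(all(c("F", "fpA", "npA") %in% names(table)))
  if (!is.null(exclude_groups)) {
    stopifnot("group" %in% names(table))
    table <- table[!(table$group %in% exclude_groups), , drop = FALSE]
  }
  table <- table[stats::complete.cases(table[, c("F", "fpA", "npA")]), ]
  if (nrow(table) < 3L) stop("correlate_f_private: need >= 3 breeds")
  c(r_F_fpA = stats::cor(table$F, table$fpA),
    r_F_npA = stats::cor(table$F, table$npA))
}
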