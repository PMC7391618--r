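#' Marker and sample quality control
#'
#' The canonical filter sequence for a multi-breed SNP-array panel:
#' individuals by call rate, then SNPs by call rate, then minor allele
#' frequency over the pooled dataset, then an exact Hardy-Weinberg test
#' within breed. The order is fixed; re-running any filter on its own
#' output is a no-op.
#'
#' @name qc
NULL

qc_report <- function(rule, removed, threshold, before, after) {
  structure(list(rule = rule, removed = removed, threshold = threshold,
                 dim_before = before, dim_after = after),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc[%s] threshold=%s removed=%d (%dx%d -> %dx%d)\n",
              x$rule, format(x$threshold), length(x$removed),
              x$dim_before[1L], x$dim_before[2L],
              x$dim_after[1L], x$dim_after[2L]))
  invisible(x)
}

subset_genotypes <- function(g, keep_ind = NULL, keep_snp = NULL) {
  d <- g$dosage
  if (!is.null(keep_ind)) d <- d[keep_ind, , drop = FALSE]
  map <- g$map
  if (!is.null(keep_snp)) {
    d <- d[, keep_snp, drop = FALSE]
    map <- marker_map(map$snp_id[keep_snp], map$chrom[keep_snp],
                      map$pos_bp[keep_snp])
  }
  genotype_matrix(d, map, rownames(d))
}

#' Filter individuals by genotype call rate
#'
#' Retains individuals whose fraction of non-missing genotypes is strictly
#' higher than `threshold` (0.95 by default).
#'
#' @param g a `genotype_matrix`.
#' @param threshold call-rate cut-off in (0, 1].
#' @return List with the filtered `genotypes` and a `report`.
#' @export
filter_sample_call_rate <- function(g, threshold = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"), threshold > 0, threshold <= 1)
  cr <- rowMeans(!is.na(g$dosage))
  keep <- cr > threshold
  if (!any(keep)) stop("filter_sample_call_rate: no individual survives")
  out <- subset_genotypes(g, keep_ind = keep)
  list(genotypes = out,
       report = qc_report("sample_call_rate", g$ids[!keep], threshold,
                          dim(g$dosage), dim(out$dosage)))
}

#' Filter SNPs by call rate
#'
#' Removes SNPs genotyped in less than `threshold` (default 0.90) of the
#' samples; a SNP typed in exactly 90% is retained.
#'
#' @inheritParams filter_sample_call_rate
#' @export
filter_snp_call_rate <- function(g, threshold = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"), threshold > 0, threshold <= 1)
  cr <- colMeans(!is.na(g$dosage))
  keep <- cr >= threshold
  if (!any(keep)) stop("filter_snp_call_rate: no SNP survives")
  out <- subset_genotypes(g, keep_snp = keep)
  list(genotypes = out,
       report = qc_report("snp_call_rate", g$map$snp_id[!keep], threshold,
                          dim(g$dosage), dim(out$dosage)))
}

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed over all non-missing genotypes pooled across breeds;
#' SNPs with MAF strictly below `threshold` (default 0.025) are removed,
#' which also discards monomorphic SNPs.
#'
#' @inheritParams filter_sample_call_rate
#' @export
filter_maf <- function(g, threshold = 0.025) {
  stopifnot(inherits(g, "genotype_matrix"), threshold >= 0, threshold <= 0.5)
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- maf >= threshold
  if (!any(keep)) stop("filter_maf: no SNP survives")
  out <- subset_genotypes(g, keep_snp = keep)
  list(genotypes = out,
       report = qc_report("maf", g$map$snp_id[!keep], threshold,
                          dim(g$dosage), dim(out$dosage)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts compatible with the allele counts are enumerated,
#' their conditional probabilities computed, and the p-value is the sum of
#' the probabilities not exceeding that of the observed configuration
#' (probability-ordering definition). Suitable for the very small breed
#' sizes (down to 4) where the chi-square approximation fails.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return The exact p-value, or `NA` when no individual was typed.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) return(NA_real_)
  nA <- 2L * n_AA + n_Aa          # copies of the A allele
  # heterozygote counts share the parity of nA and cannot exceed min(nA, 2n-nA)
  hmax <- min(nA, 2L * n - nA)
  hs <- seq(nA %% 2L, hmax, by = 2L)
  # log conditional probability of each het count given allele counts
  lp <- lchoose(n, hs) + lchoose(n - hs, (nA - hs) / 2) + hs * log(2) -
    lchoose(2L * n, nA)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= p_obs + 1e-12])
}

#' Filter SNPs by within-breed Hardy-Weinberg departures
#'
#' A SNP is removed when the exact test rejects (p <= `alpha`) in at least
#' one breed with at least `min_n` genotyped individuals at that SNP;
#' breeds below `min_n` are never allowed to trigger removal so that tiny
#' samples cannot discard markers.
#'
#' @param g a `genotype_matrix`.
#' @param breeds a `breed_assignment` covering `g$ids`.
#' @param alpha significance cut-off (default 0.01).
#' @param min_n minimum breed sample size for the test (default 10).
#' @return List with filtered `genotypes` and a `report`.
#' @export
filter_hwe_within_breed <- function(g, breeds, alpha = 0.01, min_n = 10L) {
  stopifnot(inherits(g, "genotype_matrix"))
  br <- breed_of(breeds, g$ids)
  fail <- rep(FALSE, ncol(g$dosage))
  for (b in unique(br)) {
    d <- g$dosage[br == b, , drop = FALSE]
    for (k in which(!fail)) {
      x <- d[, k]; x <- x[!is.na(x)]
      if (length(x) < min_n) next
      p <- hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
      if (!is.na(p) && p <= alpha) fail[k] <- TRUE
    }
  }
  out <- subset_genotypes(g, keep_snp = !fail)
  list(genotypes = out,
       report = qc_report("hwe_within_breed", g$map$snp_id[fail], alpha,
                          dim(g$dosage), dim(out$dosage)))
}

#' Run the full QC sequence
#'
#' Applies the four filters in their fixed order and collects reports.
#'
#' @param g a `genotype_matrix`.
#' @param breeds a `breed_assignment` (required for the HWE step).
#' @param sample_cr,snp_cr,maf,hwe_alpha,hwe_min_n thresholds; see the
#'   individual filters.
#' @return List with `genotypes` and `reports` (list of `qc_report`s).
#' @export
run_qc <- function(g, breeds, sample_cr = 0.95, snp_cr = 0.90,
                   maf = 0.025, hwe_alpha = 0.01, hwe_min_n = 10L) {
  r1 <- filter_sample_call_rate(g, sample_cr)
  r2 <- filter_snp_call_rate(r1$genotypes, snp_cr)
  r3 <- filter_maf(r2$genotypes, maf)
  r4 <- filter_hwe_within_breed(r3$genotypes, breeds, hwe_alpha, hwe_min_n)
  list(genotypes = r4$genotypes,
       reports = list(r1$report, r2$report, r3$report, r4$report))
}
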