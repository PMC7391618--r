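#' Patterson's D from population allele frequencies
#'
#' Four-population test of treeness for (((P1,P2),P3),O). In the frequency
#' (population-panel) form,
#' \deqn{D = \frac{\sum_k (p_{2k} - p_{1k})(p_{3k} - p_{Ok})}
#'   {\sum_k (p_{1k} + p_{2k} - 2 p_{1k} p_{2k})
#'     (p_{3k} + p_{Ok} - 2 p_{3k} p_{Ok})},}
#' which reduces to the normalised ABBA minus BABA site-pattern count when
#' all frequencies are 0 or 1 (a pure ABBA site contributes +1). Sites
#' where all four frequencies are equal carry no signal and are skipped.
#' The sign convention is "ABBA-positive": D > 0 means excess allele
#' sharing between P2 and P3, D < 0 between P1 and P3; swapping P1 and P2
#' negates D. Significance is judged two-sided on |Z|.
#'
#' @param p1,p2,p3,pO aligned per-SNP alternate-allele frequency vectors.
#' @return List with `D`, the accumulations `num`/`den` and the per-site
#'   components (`num_k`, `den_k`) for jackknifing; `D` is `NA` when the
#'   denominator is zero.
#' @export
d_statistic <- function(p1, p2, p3, pO) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(pO))
  skip <- p1 == p2 & p2 == p3 & p3 == pO
  num_k <- (p2 - p1) * (p3 - pO)
  den_k <- (p1 + p2 - 2 * p1 * p2) * (p3 + pO - 2 * p3 * pO)
  num_k[skip] <- 0; den_k[skip] <- 0
  num <- sum(num_k); den <- sum(den_k)
  list(D = if (den > 0) num / den else NA_real_,
       num = num, den = den, num_k = num_k, den_k = den_k,
       n_sites = sum(!skip))
}

#' Weighted block jackknife for Patterson's D
#'
#' Delete-one-block estimates over genomic windows with the weighted
#' jackknife of Busing et al., weights proportional to per-block site
#' counts, as used for D statistics on whole-genome panels. Blocks of
#' 5 Mb comfortably exceed the LD range of cattle.
#'
#' @param num_k,den_k per-site components from [d_statistic()].
#' @param pos_bp,chrom per-site physical position and chromosome.
#' @param block_bp jackknife window size (default 5e6).
#' @param min_blocks smallest acceptable number of non-empty blocks
#'   (default 20); set lower only for toy inputs.
#' @return List with `D`, `se`, `z` (`Inf` sentinel when the jackknife
#'   variance is exactly zero) and `n_blocks`.
#' @export
block_jackknife <- function(num_k, den_k, pos_bp, chrom = NULL,
                            block_bp = 5e6, min_blocks = 20L) {
  if (is.null(chrom)) chrom <- rep("1", length(pos_bp))
  blk <- paste(chrom, floor((pos_bp - 1) / block_bp), sep = ":")
  informative <- den_k != 0
  blocks <- sort(unique(blk[informative]))
  g <- length(blocks)
  if (g < min_blocks)
    stop(sprintf("block_jackknife: only %d non-empty blocks (< %d); use more data or smaller blocks",
                 g, min_blocks))
  tot_num <- sum(num_k); tot_den <- sum(den_k)
  D <- tot_num / tot_den
  bnum <- vapply(blocks, function(b) sum(num_k[blk == b]), numeric(1))
  bden <- vapply(blocks, function(b) sum(den_k[blk == b]), numeric(1))
  m_j <- vapply(blocks, function(b) sum(informative & blk == b), numeric(1))
  n <- sum(m_j)
  theta_mj <- (tot_num - bnum) / (tot_den - bden)   # delete-one estimates
  h_j <- n / m_j
  theta_dot <- g * D - sum((1 - m_j / n) * theta_mj)
  tau <- h_j * D - (h_j - 1) * theta_mj             # pseudovalues
  var_j <- sum((tau - theta_dot)^2 / (h_j - 1)) / g
  se <- sqrt(var_j)
  z <- if (se == 0) { if (D == 0) 0 else sign(D) * Inf } else D / se
  list(D = D, se = se, z = z, n_blocks = g)
}

#' Breed allele frequencies at bi-allelic SNPs
#'
#' @param g a `genotype_matrix`.
#' @param breeds a `breed_assignment`.
#' @param breed breed code.
#' @return Per-SNP alternate-allele frequency vector for that breed.
#' @export
breed_snp_frequencies <- function(g, breeds, breed) {
  br <- breed_of(breeds, g$ids)
  sel <- br == breed
  if (!any(sel)) stop("breed_snp_frequencies: unknown or empty breed ", breed)
  colMeans(g$dosage[sel, , drop = FALSE], na.rm = TRUE) / 2
}

#' ABBA-BABA scan over candidate P1 breeds
#'
#' Computes Patterson's D with block-jackknife Z for the configuration
#' (((P1, P2), P3), O) for every breed in `p1_list`, holding P2, P3 and
#' the outgroup fixed (the taurine-indicine design: outgroup yak, P3 an
#' indicine breed, P2 a breed assumed free of indicine ancestry).
#' Results with |Z| > 3 are flagged significant.
#'
#' @param g a `genotype_matrix` for all breeds.
#' @param breeds a `breed_assignment`.
#' @param outgroup,p3,p2 breed codes.
#' @param p1_list character vector of P1 breed codes.
#' @param block_bp,min_blocks passed to [block_jackknife()].
#' @return `data.frame` with one row per P1: `D`, `se`, `z`, `n_blocks`,
#'   `significant`.
#' @export
dstat_scan <- function(g, breeds, outgroup, p3, p2, p1_list,
                       block_bp = 5e6, min_blocks = 20L) {
  for (b in c(outgroup, p3, p2, p1_list))
    if (!b %in% breeds$breed) stop("dstat_scan: unknown breed ", b)
  if (!length(p1_list))
    return(data.frame(P1 = character(0), P2 = character(0), P3 = character(0),
                      O = character(0), D = numeric(0), se = numeric(0),
                      z = numeric(0), n_blocks = integer(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  pO <- breed_snp_frequencies(g, breeds, outgroup)
  f3 <- breed_snp_frequencies(g, breeds, p3)
  f2 <- breed_snp_frequencies(g, breeds, p2)
  out <- lapply(p1_list, function(b1) {
    f1 <- breed_snp_frequencies(g, breeds, b1)
    ds <- d_statistic(f1, f2, f3, pO)
    jk <- block_jackknife(ds$num_k, ds$den_k, g$map$pos_bp, g$map$chrom,
                          block_bp, min_blocks)
    data.frame(P1 = b1, P2 = p2, P3 = p3, O = outgroup,
               D = jk$D, se = jk$se, z = jk$z, n_blocks = jk$n_blocks,
               significant = is.finite(jk$z) && abs(jk$z) > 3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
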