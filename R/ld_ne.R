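#' Pairwise r-squared between SNPs of one breed
#'
#' Squared Pearson correlation of allele indicators across haplotype rows,
#' for all intra-chromosomal SNP pairs whose physical distance lies in
#' `[d_min, d_max]` (20 kb to 10 Mb by default, the range informative for
#' recent to domestication-era effective population size). SNPs
#' monomorphic within the breed are skipped, as are SNPs below the `maf`
#' threshold (low-frequency sites constrain r2 from above and bias the
#' decay curve). With phased haplotypes this equals the classical
#' \eqn{D^2 / [p(1-p) q(1-q)]}.
#'
#' @param h a `haplotype_matrix` restricted to one breed.
#' @param d_min,d_max distance bounds in bp (inclusive).
#' @param maf within-breed minor-allele-frequency filter (default 0.05).
#' @return `data.frame` with columns `snp1`, `snp2`, `dist_bp`, `r2` and
#'   attribute `n_ind` (individuals).
#' @export
pairwise_r2 <- function(h, d_min = 20000, d_max = 10000000, maf = 0.05) {
  stopifnot(inherits(h, "haplotype_matrix"))
  if (length(h$ids) < 2L) stop("pairwise_r2: need >= 2 individuals")
  out <- vector("list", 0L)
  for (ch in unique(h$map$chrom)) {
    idx <- which(h$map$chrom == ch)
    if (length(idx) < 2L) next
    a <- h$alleles[, idx, drop = FALSE]
    p <- colMeans(a)
    poly <- pmin(p, 1 - p) >= maf & p > 0 & p < 1
    idx <- idx[poly]; a <- a[, poly, drop = FALSE]
    if (length(idx) < 2L) next
    pos <- h$map$pos_bp[idx]
    cc <- suppressWarnings(stats::cor(a))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dist <- pos[pr[, 2L]] - pos[pr[, 1L]]
    keep <- dist >= d_min & dist <= d_max
    if (!any(keep)) next
    pr <- pr[keep, , drop = FALSE]; dist <- dist[keep]
    out[[length(out) + 1L]] <- data.frame(
      snp1 = h$map$snp_id[idx[pr[, 1L]]],
      snp2 = h$map$snp_id[idx[pr[, 2L]]],
      dist_bp = dist,
      r2 = cc[pr]^2,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp1 = character(0), snp2 = character(0),
               dist_bp = numeric(0), r2 = numeric(0))
  attr(res, "n_ind") <- length(h$ids)
  res
}

#' Physical distance to recombination fraction
#'
#' Default linear genome-wide map: `c = d * rate * 1e-8` with `rate` in
#' cM/Mb; a Haldane option maps through `0.5 * (1 - exp(-2 d rate 1e-8))`.
#' Values reaching 0.5 are clamped with a warning.
#'
#' @param d distance(s) in bp.
#' @param mapping `"linear"` or `"haldane"`.
#' @param rate recombination rate in cM/Mb (default 1).
#' @return Recombination fraction(s).
#' @export
distance_to_c <- function(d, mapping = c("linear", "haldane"), rate = 1.0) {
  mapping <- match.arg(mapping)
  stopifnot(all(d > 0))
  m <- d * rate * 1e-8
  cc <- if (mapping == "linear") m else 0.5 * (1 - exp(-2 * m))
  if (any(cc >= 0.5)) {
    warning("distance_to_c: recombination fraction clamped below 0.5")
    cc <- pmin(cc, 0.5 - 1e-9)
  }
  cc
}

#' LD-decay curve of historical effective population size
#'
#' Bins SNP-pair r-squared records into `bins` log-spaced distance classes,
#' applies the sample-size correction `r2_adj = r2 - 1/(beta * n)` (with
#' `beta = 2` for phased haplotype input) and converts each bin's mean to
#' \deqn{N_e(t) = \frac{1}{4 f(c)} \left(\frac{1}{E[r^2_{adj}]} -
#'   \alpha\right), \qquad t = \frac{1}{2 f(c)},}
#' with `f(c)` the bin's harmonic-mean recombination fraction and `alpha`
#' the mutation adjustment (2 when mutation is ignored, 2.2 otherwise).
#' The reported `Ne_5`, `Ne_50`, `Ne_2000` are the curve values whose
#' generation times are nearest 5, 50 and 2000.
#'
#' @param records output of [pairwise_r2()].
#' @param n number of diploid individuals behind the records.
#' @param alpha mutation adjustment constant.
#' @param beta sample-size correction divisor.
#' @param bins number of log-spaced distance bins.
#' @param mapping,rate passed to [distance_to_c()].
#' @return List of class `ne_curve` with the per-bin `curve` data.frame
#'   and scalars `Ne_5`, `Ne_50`, `Ne_2000`.
#' @export
ne_curve <- function(records, n, alpha = 2, beta = 2, bins = 30L,
                     mapping = "linear", rate = 1.0) {
  if (nrow(records) == 0L) stop("ne_curve: no records")
  stopifnot(n >= 2)
  r2a <- records$r2 - 1 / (beta * n)
  cs <- distance_to_c(records$dist_bp, mapping, rate)
  rng <- range(records$dist_bp)
  brk <- exp(seq(log(rng[1L]), log(rng[2L]), length.out = bins + 1L))
  brk[1L] <- brk[1L] - 1; brk[bins + 1L] <- brk[bins + 1L] + 1
  bin <- cut(records$dist_bp, brk, labels = FALSE)
  curve <- do.call(rbind, lapply(seq_len(bins), function(k) {
    sel <- bin == k
    if (!any(sel)) return(NULL)
    ch <- 1 / mean(1 / cs[sel])              # harmonic-mean c
    er2 <- mean(r2a[sel])
    ne <- if (er2 > 0 && 1 / er2 > alpha) (1 / (4 * ch)) * (1 / er2 - alpha)
          else NA_real_
    data.frame(bin = k, n_pairs = sum(sel), c = ch, t = 1 / (2 * ch),
               mean_r2_adj = er2, Ne = ne)
  }))
  pick <- function(tgt) {
    ok <- which(!is.na(curve$Ne))
    if (!length(ok)) return(NA_real_)
    curve$Ne[ok[which.min(abs(log(curve$t[ok]) - log(tgt)))]]
  }
  structure(list(curve = curve, Ne_5 = pick(5), Ne_50 = pick(50),
                 Ne_2000 = pick(2000), alpha = alpha, beta = beta, n = n),
            class = "ne_curve")
}

#' Breed-level Ne estimation from phased haplotypes
#'
#' Convenience wrapper: subsets a cohort's haplotypes to one breed, runs
#' [pairwise_r2()] and [ne_curve()]. Breeds below `min_n` individuals give
#' `NA` estimates (LD in tiny samples is dominated by sampling noise).
#'
#' @param h cohort `haplotype_matrix`.
#' @param breeds a `breed_assignment`.
#' @param breed breed code.
#' @param min_n smallest breed analysed (default 8).
#' @param ... passed to [ne_curve()].
#' @return An `ne_curve`, or `NULL` when the breed is too small.
#' @export
breed_ne <- function(h, breeds, breed, min_n = 8L, ...) {
  br <- breed_of(breeds, h$ids)
  sel <- which(br == breed)
  if (length(sel) < min_n) return(NULL)
  rows <- sort(c(2L * sel - 1L, 2L * sel))
  hb <- haplotype_matrix(h$alleles[rows, , drop = FALSE], h$map, h$ids[sel])
  rec <- pairwise_r2(hb)
  if (nrow(rec) == 0L) return(NULL)
  ne_curve(rec, n = length(sel), ...)
}

#' Nd-weighted group means of Ne columns
#'
#' Weighted means of `Ne5`, `Ne50`, `Ne2000` (or any subset present) over
#' the breeds of each group, excluding breeds whose Ne is undefined.
#'
#' @param table per-breed `data.frame` with `breed`, `Nd` and Ne columns.
#' @param breeds a `breed_assignment` mapping breeds to groups.
#' @return `data.frame` of group means.
#' @export
group_ne_summary <- function(table, breeds) {
  necols <- intersect(c("Ne5", "Ne50", "Ne2000"), names(table))
  if (!length(necols)) stop("group_ne_summary: no Ne columns present")
  group_weighted_summary(table, breeds, stats = necols)
}
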