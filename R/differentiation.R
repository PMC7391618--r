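#' Pairwise Jost's D for two breeds
#'
#' Jost's differentiation measure for multi-allelic markers, preferred over
#' G_ST-type indices when within-population gene diversity is high.
#' Sample-size bias is handled with the standard corrections: with
#' harmonic-mean breed size \eqn{\tilde N} (individuals),
#' \deqn{\hat H_S = \frac{2\tilde N}{2\tilde N - 1}
#'   \Big(1 - \mathrm{mean}_d \sum_u p_{du}^2\Big), \quad
#'   \hat H_T = 1 - \sum_u \bar p_u^2 + \frac{\hat H_S}{4 \tilde N},}
#' and for n = 2 demes \eqn{D = \frac{\hat H_T - \hat H_S}{1 - \hat H_S}
#'   \cdot \frac{n}{n-1}}.
#' Across blocks, either the components are averaged first
#' (`aggregate = "components"`, the stabler default) or the per-block D
#' values are averaged (`aggregate = "per_locus_mean"`). Slightly negative
#' estimates are clamped to zero.
#'
#' @param t a `block_allele_table`.
#' @param a,b breed codes present in `t`.
#' @param aggregate multi-block aggregation rule.
#' @return The D estimate in `[0, 1]`.
#' @export
dest_pairwise <- function(t, a, b, aggregate = c("components", "per_locus_mean")) {
  stopifnot(inherits(t, "block_allele_table"))
  aggregate <- match.arg(aggregate)
  if (!all(c(a, b) %in% t$breeds)) stop("dest_pairwise: unknown breed")
  Na <- t$n_ind[[a]]; Nb <- t$n_ind[[b]]
  Nh <- 2 / (1 / Na + 1 / Nb)
  hs <- ht <- dv <- numeric(length(t$counts))
  for (j in seq_along(t$counts)) {
    cm <- t$counts[[j]]
    pa <- cm[, a] / t$copies[[a]]
    pb <- cm[, b] / t$copies[[b]]
    hs_j <- (2 * Nh / (2 * Nh - 1)) * (1 - mean(c(sum(pa^2), sum(pb^2))))
    pm <- (pa + pb) / 2
    ht_j <- 1 - sum(pm^2) + hs_j / (4 * Nh)
    hs[j] <- hs_j; ht[j] <- ht_j
    dv[j] <- if (ht_j >= 1) 0 else 2 * (ht_j - hs_j) / (1 - hs_j)
  }
  d <- if (aggregate == "components") {
    HS <- mean(hs); HT <- mean(ht)
    2 * (HT - HS) / (1 - HS)
  } else mean(dv)
  max(0, min(1, d))
}

#' Full pairwise D_EST matrix
#'
#' @param t a `block_allele_table`.
#' @param aggregate see [dest_pairwise()].
#' @return Symmetric breed-by-breed matrix with zero diagonal, class
#'   `dest_matrix`.
#' @export
dest_matrix <- function(t, aggregate = "components") {
  br <- t$breeds
  m <- matrix(0, length(br), length(br), dimnames = list(br, br))
  for (i in seq_along(br)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- dest_pairwise(t, br[i], br[j], aggregate)
  }
  class(m) <- c("dest_matrix", class(m))
  m
}

#' Group and per-breed summaries of a D_EST matrix
#'
#' Unweighted means over pair sets: per breed the mean D to all other
#' breeds; per group the mean over distinct within-group pairs (absent for
#' single-breed groups).
#'
#' @param m a breed-by-breed `dest_matrix`.
#' @param breeds a `breed_assignment` mapping breeds to groups.
#' @return List with `per_breed` and `within_group` named vectors.
#' @export
dest_summaries <- function(m, breeds) {
  br <- rownames(m)
  per_breed <- stats::setNames(
    vapply(seq_along(br), function(i) mean(m[i, -i]), numeric(1)), br)
  grp <- breeds$group[match(br, breeds$breed)]
  wg <- vapply(unique(grp), function(g) {
    sel <- which(grp == g)
    if (length(sel) < 2L) return(NA_real_)
    mean(m[sel, sel][lower.tri(matrix(0, length(sel), length(sel)))])
  }, numeric(1))
  list(per_breed = per_breed,
       within_group = stats::setNames(wg, unique(grp)))
}

#' Allele-sharing distance between individuals
#'
#' For a pair of individuals at one block, the number of alleles shared
#' between their two unordered genotypes is 0, 1 or 2 (multiset
#' intersection); PS is the mean of shared/2 over blocks and
#' `D_PS = 1 - PS`.
#'
#' @param bg `block_genotypes`.
#' @return Symmetric individual-by-individual matrix of class `dps_matrix`.
#' @export
allele_sharing_distance <- function(bg) {
  stopifnot(inherits(bg, "block_genotypes"))
  n <- length(bg$ids); nb <- ncol(bg$a1)
  ps <- matrix(0, n, n, dimnames = list(bg$ids, bg$ids))
  for (j in seq_len(nb)) {
    x1 <- bg$a1[, j]; x2 <- bg$a2[, j]
    # shared(i,k) via pairwise comparisons of the two unordered pairs
    s11 <- outer(x1, x1, "=="); s12 <- outer(x1, x2, "==")
    s21 <- outer(x2, x1, "=="); s22 <- outer(x2, x2, "==")
    # multiset intersection size of {x1,x2}_i and {x1,x2}_k
    both <- (s11 & s22) | (s12 & s21)          # at least a perfect matching of 2
    any1 <- s11 | s12 | s21 | s22
    shared <- matrix(0L, n, n)
    shared[any1] <- 1L
    shared[both] <- 2L
    # one shared allele when exactly one symbol matches; two identical
    # homozygotes are caught by `both`; het vs hom sharing one allele by `any1`
    ps <- ps + shared / 2
  }
  d <- 1 - ps / nb
  diag(d) <- 0
  class(d) <- c("dps_matrix", class(d))
  d
}

#' Mean within-breed allele-sharing distance
#'
#' Average D_PS over distinct within-breed pairs; a proxy for breed-level
#' differentiation (low values mean strongly homogeneous, drifted breeds).
#' Singleton breeds get `NA`.
#'
#' @param d a `dps_matrix`.
#' @param breeds a `breed_assignment`.
#' @return Named per-breed vector.
#' @export
mean_within_breed_dps <- function(d, breeds) {
  ids <- rownames(d)
  br <- breed_of(breeds, ids)
  vapply(sort(unique(br)), function(b) {
    sel <- which(br == b)
    if (length(sel) < 2L) return(NA_real_)
    mean(d[sel, sel][lower.tri(matrix(0, length(sel), length(sel)))])
  }, numeric(1))
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Thin wrapper over [stats::cmdscale()] with a deterministic sign
#' convention (the largest-magnitude loading of each axis is made
#' positive); coordinates are otherwise defined only up to
#' rotation/reflection. When fewer than `k` positive eigenvalues exist the
#' dimensionality is reduced with a warning.
#'
#' @param d symmetric zero-diagonal distance matrix.
#' @param k target dimensionality (default 2).
#' @return Matrix of coordinates (rows match `d`).
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k)
    warning(sprintf("classical_mds: only %d positive eigenvalue(s); reduced from k=%d",
                    ncol(pts), k))
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  pts
}

#' Breed centers and dispersion radii in an MDS plane
#'
#' The breed center is the mean coordinate of its members; each member's
#' planar (Euclidean) distance to the center is computed and the breed's
#' dispersion radius is the standard deviation of those distances, the
#' radius drawn around the breed symbol in MDS plots. Singletons get
#' radius 0.
#'
#' @param coords coordinate matrix (individuals x 2) from
#'   [classical_mds()].
#' @param breeds a `breed_assignment`.
#' @return `data.frame` with per-breed center coordinates and `radius`.
#' @export
breed_dispersion <- function(coords, breeds) {
  stopifnot(ncol(coords) >= 2L)
  ids <- rownames(coords)
  br <- breed_of(breeds, ids)
  out <- lapply(sort(unique(br)), function(b) {
    xy <- coords[br == b, 1:2, drop = FALSE]
    ctr <- colMeans(xy)
    dist <- sqrt(rowSums(sweep(xy, 2L, ctr, "-")^2))
    data.frame(breed = b, x = ctr[1L], y = ctr[2L],
               radius = if (length(dist) > 1L) stats::sd(dist) else 0,
               n = nrow(xy), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
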