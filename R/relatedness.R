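#' Alternate-allele frequencies
#'
#' Frequencies over all non-missing genotypes of the full (post-QC) cohort;
#' these centre the UAR matrix. Monomorphic SNPs are an error here because
#' the MAF filter should have removed them and they would divide by zero in
#' the relationship formulas.
#'
#' @param g a `genotype_matrix`.
#' @return Numeric vector of per-SNP alternate-allele frequencies.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("allele_frequencies: monomorphic or untyped SNP present; run QC first")
  p
}

#' Unified additive relationship (UAR) matrix
#'
#' Genome-wide additive relationships from SNP dosages `x` centred at
#' frequencies `p`. The off-diagonal entry for individuals i, j is the mean
#' over SNPs of
#' \deqn{(x_{ik} - 2p_k)(x_{jk} - 2p_k) / (2 p_k (1 - p_k)),}
#' and the diagonal is
#' \deqn{1 + \mathrm{mean}_k [x_{ik}^2 - (1 + 2p_k) x_{ik} + 2p_k^2] /
#'   [2 p_k (1 - p_k)],}
#' so that `UAR[i,i] - 1` is the genomic inbreeding coefficient of i.
#' Residual missing dosages are mean-imputed at `2 p_k` (i.e. contribute
#' zero) and counted in the `n_imputed` attribute.
#'
#' @param g a `genotype_matrix` (ideally QC-complete).
#' @param p frequencies from [allele_frequencies()]; computed when `NULL`.
#' @return Symmetric matrix of class `uar_matrix` with individual ids as
#'   dimnames.
#' @export
uar_matrix <- function(g, p = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(p)) p <- allele_frequencies(g)
  if (any(p <= 0) || any(p >= 1)) stop("uar_matrix: frequencies must be in (0,1)")
  x <- g$dosage
  m <- ncol(x)
  n_imputed <- sum(is.na(x))
  denom <- 2 * p * (1 - p)
  xc <- sweep(x, 2L, 2 * p, "-")
  xc[is.na(xc)] <- 0                      # mean imputation: centred value 0
  w <- sweep(xc, 2L, sqrt(denom), "/")
  u <- tcrossprod(w) / m
  # diagonal by its own formula (not the square of the centred dosage)
  xi <- x
  xi[is.na(xi)] <- matrix(2 * p, nrow = nrow(x), ncol = m, byrow = TRUE)[is.na(xi)]
  dnum <- xi^2 - sweep(xi, 2L, 1 + 2 * p, "*") +
    matrix(2 * p^2, nrow = nrow(x), ncol = m, byrow = TRUE)
  diag(u) <- 1 + rowMeans(sweep(dnum, 2L, denom, "/"))
  dimnames(u) <- list(g$ids, g$ids)
  attr(u, "n_imputed") <- n_imputed
  class(u) <- c("uar_matrix", class(u))
  u
}

#' Inbreeding coefficients from a UAR matrix
#'
#' @param u a `uar_matrix`.
#' @return Named vector `F = diag(u) - 1`.
#' @export
inbreeding_from_uar <- function(u) {
  diag(unclass(u)) - 1
}

#' Multivariate outlier detection within breeds
#'
#' Flags erroneously sampled or strongly admixed animals. Each breed's
#' sub-matrix of the UAR is embedded by principal coordinates (eigenvectors
#' of the double-centred relationship scaled by the root eigenvalues, top
#' `k_dims` positive axes); a robust squared distance is formed by
#' standardising each axis with median and MAD and compared with the
#' chi-square upper-`alpha` quantile on the number of axes used. Breeds
#' with fewer than `min_n` members are skipped and logged.
#'
#' @param u a `uar_matrix`.
#' @param breeds a `breed_assignment` covering the matrix ids.
#' @param k_dims number of principal coordinates (default 5).
#' @param alpha flagging quantile (default 0.025).
#' @param min_n smallest breed tested (default 5).
#' @return Logical vector of flags named by id; attribute `skipped` lists
#'   breeds too small to test.
#' @export
detect_outliers <- function(u, breeds, k_dims = 5L, alpha = 0.025, min_n = 5L) {
  ids <- rownames(u)
  br <- breed_of(breeds, ids)
  flags <- stats::setNames(rep(FALSE, length(ids)), ids)
  skipped <- character(0)
  for (b in unique(br)) {
    sel <- which(br == b)
    if (length(sel) < min_n) { skipped <- c(skipped, b); next }
    ub <- unclass(u)[sel, sel, drop = FALSE]
    n <- nrow(ub)
    cmat <- diag(n) - matrix(1 / n, n, n)
    e <- eigen(cmat %*% ub %*% cmat, symmetric = TRUE)
    pos <- which(e$values > 1e-9)
    k <- min(k_dims, length(pos))
    if (k < 1L) next
    coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(k)]]), k)
    z <- apply(coords, 2L, function(v) {
      s <- stats::mad(v)
      if (s < 1e-12) s <- stats::sd(v)   # degenerate axes (e.g. near-clones)
      if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
      (v - stats::median(v)) / s
    })
    d2 <- rowSums(as.matrix(z)^2)
    flags[sel] <- d2 > stats::qchisq(1 - alpha, df = k)
  }
  attr(flags, "skipped") <- skipped
  flags
}

#' Greedy pruning of highly related animals
#'
#' While any within-breed off-diagonal relationship exceeds `threshold`
#' (default 0.45, about first-degree relatives), the individual with the
#' most above-threshold partners is removed; ties go to the larger mean
#' relationship among its above-threshold partners, then to the
#' lexicographically smaller id. Every removal is recorded. Outliers are
#' assumed to have been excluded already.
#'
#' @param u a `uar_matrix`.
#' @param breeds a `breed_assignment`; relationships are only compared
#'   within breed.
#' @param threshold relationship cut-off.
#' @return List of class `prune_result` with `kept`, `removed`
#'   (data.frame of id/reason), `threshold` and the per-iteration `log`.
#' @export
prune_related <- function(u, breeds, threshold = 0.45) {
  ids <- rownames(u)
  br <- breed_of(breeds, ids)
  um <- unclass(u)
  active <- stats::setNames(rep(TRUE, length(ids)), ids)
  same_breed <- outer(br, br, "==")
  high <- um > threshold & same_breed
  diag(high) <- FALSE
  log <- list()
  repeat {
    sub <- high & outer(active, active, "&")
    cnt <- rowSums(sub)
    if (all(cnt == 0L)) break
    mx <- max(cnt)
    cand <- which(cnt == mx)
    if (length(cand) > 1L) {
      meanrel <- vapply(cand, function(i) mean(um[i, sub[i, ]]), numeric(1))
      cand <- cand[meanrel == max(meanrel)]
      if (length(cand) > 1L) cand <- cand[order(ids[cand])][1L]
    }
    drop <- cand[1L]
    active[drop] <- FALSE
    log[[length(log) + 1L]] <- list(id = ids[drop], n_partners = mx)
  }
  removed <- ids[!active]
  structure(list(kept = ids[active],
                 removed = if (length(removed))
                   data.frame(id = removed, reason = "related",
                              stringsAsFactors = FALSE)
                 else data.frame(id = character(0), reason = character(0)),
                 threshold = threshold, log = log),
            class = "prune_result")
}
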