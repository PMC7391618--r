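#' Nei's D_A distance between two breeds
#'
#' \deqn{D_A = 1 - \frac{1}{L} \sum_{l} \sum_u \sqrt{x_{lu} y_{lu}}}
#' over the `L` shared blocks, where `x`, `y` are the two breeds' block
#' allele frequencies. Zero for identical frequency tables, one for breeds
#' fixed for disjoint alleles everywhere.
#'
#' @param t a `block_allele_table`.
#' @param a,b breed codes.
#' @return The D_A distance.
#' @export
nei_da <- function(t, a, b) {
  stopifnot(inherits(t, "block_allele_table"))
  if (!all(c(a, b) %in% t$breeds)) stop("nei_da: unknown breed")
  s <- 0
  for (j in seq_along(t$counts)) {
    cm <- t$counts[[j]]
    s <- s + sum(sqrt((cm[, a] / t$copies[[a]]) * (cm[, b] / t$copies[[b]])))
  }
  1 - s / length(t$counts)
}

#' Full Nei D_A matrix
#'
#' @param t a `block_allele_table`.
#' @return Symmetric breed-by-breed distance matrix, class `da_matrix`.
#' @export
nei_da_matrix <- function(t) {
  br <- t$breeds
  m <- matrix(0, length(br), length(br), dimnames = list(br, br))
  for (i in seq_along(br)) for (j in seq_len(i - 1L))
    m[i, j] <- m[j, i] <- nei_da(t, br[i], br[j])
  class(m) <- c("da_matrix", class(m))
  m
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimising the
#' Q-criterion
#' \deqn{Q(i,j) = (r - 2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}
#' with the standard branch-length formulas; ties are broken by the
#' lexicographically smallest taxon pair so the output is deterministic.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sister edge, the usual practice. For additive input the original
#' tree is recovered exactly.
#'
#' @param d symmetric distance matrix with taxon dimnames, >= 3 taxa.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(unclass(d))
  if (!isSymmetric(unname(d))) stop("neighbor_joining: matrix not symmetric")
  n <- nrow(d)
  if (n < 3L) stop("neighbor_joining: need >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  D <- d
  id_of <- seq_len(n)              # current node id per active row
  key <- labels                    # smallest tip label below, for tie-breaks
  created <- integer(0)            # internal node ids in creation order
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      pk <- apply(cand, 1L, function(ij)
        paste(sort(c(key[ij[1L]], key[ij[2L]])), collapse = "\r"))
      cand <- cand[order(pk)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }   # clamp, deficit to sister edge
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- n + length(created) + 1L
    created <- c(created, u)
    edges <- rbind(edges, c(u, id_of[i]), c(u, id_of[j]))
    lens <- c(lens, li, lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    id_of <- c(id_of[keep], u)
    key <- c(key[keep], min(key[c(i, j)]))
  }
  # terminal 3-way join onto the (trifurcating) basal node
  u <- n + length(created) + 1L
  created <- c(created, u)
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(u, id_of[1L]), c(u, id_of[2L]), c(u, id_of[3L]))
  lens <- c(lens, pmax(c(l1, l2, l3), 0))
  # renumber so the basal node is n+1 as ape expects
  K <- length(created)
  remap <- integer(n + K)
  remap[seq_len(n)] <- seq_len(n)
  remap[created] <- n + 1L + (K - match(created, created))
  tr <- list(edge = matrix(remap[edges], ncol = 2L),
             edge.length = lens,
             tip.label = labels,
             Nnode = K)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Root a tree on an outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's terminal branch;
#' leaf-to-leaf path lengths are unchanged.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup a tip label.
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(outgroup, tree$tip.label)
  if (is.na(tip)) stop("root_with_outgroup: unknown leaf ", outgroup)
  pend <- which(tree$edge[, 2L] == tip)
  pos <- tree$edge.length[pend] / 2
  phytools::reroot(tree, node.number = tip, position = pos)
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
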