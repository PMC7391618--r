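#' Build haplotype blocks of consecutive SNPs
#'
#' Greedy left-to-right scan per chromosome: the next `block_size`
#' unconsumed consecutive SNPs form a block when the block spans less than
#' `max_span` bp and every adjacent within-block gap is shorter than
#' `max_gap` bp (both strict); on success all member SNPs are consumed,
#' otherwise the window advances by one SNP (`advance = "slide"`) or jumps
#' past the failing window (`advance = "jump"`). Blocks never span
#' chromosomes and never overlap; the defaults (4 SNPs, < 150 kb span,
#' < 50 kb gaps) trade marker density against within-block recombination.
#'
#' @param map a `marker_map`, sorted within chromosome.
#' @param block_size number of SNPs per block.
#' @param max_span,max_gap span/gap bounds in bp (strict inequalities).
#' @param advance `"slide"` (default) or `"jump"`.
#' @return A `data.frame` of class `block_definition`: `block_id`, `chrom`,
#'   `start_bp`, `end_bp` and a `snp_index` matrix column of the member
#'   SNP indices into `map`.
#' @export
build_blocks <- function(map, block_size = 4L, max_span = 150000L,
                         max_gap = 50000L, advance = c("slide", "jump")) {
  stopifnot(inherits(map, "marker_map"), block_size >= 2L)
  advance <- match.arg(advance)
  out_idx <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_bp[idx]
    i <- 1L
    while (i + block_size - 1L <= length(idx)) {
      w <- i:(i + block_size - 1L)
      span <- pos[w[block_size]] - pos[w[1L]]
      gaps <- diff(pos[w])
      if (span < max_span && all(gaps < max_gap)) {
        out_idx[[length(out_idx) + 1L]] <- idx[w]
        i <- i + block_size
      } else {
        i <- i + if (advance == "slide") 1L else block_size
      }
    }
  }
  n <- length(out_idx)
  snp_index <- if (n) do.call(rbind, out_idx) else
    matrix(integer(0), 0L, block_size)
  bd <- data.frame(
    block_id = if (n) paste0("blk", seq_len(n)) else character(0),
    chrom = map$chrom[snp_index[, 1L]],
    start_bp = map$pos_bp[snp_index[, 1L]],
    end_bp = map$pos_bp[snp_index[, block_size]],
    stringsAsFactors = FALSE)
  bd$snp_index <- snp_index
  class(bd) <- c("block_definition", "data.frame")
  bd
}

#' Encode block haplotypes as multi-allelic genotypes
#'
#' For every haplotype row the member-SNP alleles of each block are
#' concatenated in map order into a word (e.g. `"0101"`); the two words of
#' an individual form its genotype at that multi-allelic marker. With
#' 4-SNP blocks at most 16 alleles per block are possible.
#'
#' @param h a `haplotype_matrix` (complete by contract).
#' @param blocks a `block_definition` from [build_blocks()].
#' @return Object of class `block_genotypes`: character matrices `a1`,
#'   `a2` (individuals x blocks) plus `ids` and the `blocks` used.
#' @export
encode_block_alleles <- function(h, blocks) {
  stopifnot(inherits(h, "haplotype_matrix"), inherits(blocks, "block_definition"))
  n <- length(h$ids)
  nb <- nrow(blocks)
  a1 <- matrix("", n, nb); a2 <- matrix("", n, nb)
  r1 <- seq(1L, 2L * n, by = 2L); r2 <- r1 + 1L
  for (j in seq_len(nb)) {
    cols <- blocks$snp_index[j, ]
    w1 <- h$alleles[r1, cols, drop = FALSE]
    w2 <- h$alleles[r2, cols, drop = FALSE]
    a1[, j] <- apply(w1, 1L, paste, collapse = "")
    a2[, j] <- apply(w2, 1L, paste, collapse = "")
  }
  rownames(a1) <- rownames(a2) <- h$ids
  colnames(a1) <- colnames(a2) <- blocks$block_id
  structure(list(a1 = a1, a2 = a2, ids = h$ids, blocks = blocks),
            class = "block_genotypes")
}
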