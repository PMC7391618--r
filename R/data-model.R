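#' Marker map
#'
#' A marker map records, for each SNP, its identifier, chromosome and 1-based
#' physical position in base pairs. Positions must be strictly increasing
#' within each chromosome and SNP identifiers unique; sex and unplaced
#' chromosomes are expected to have been removed upstream.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (coerced to character).
#' @param pos_bp integer vector of 1-based physical positions.
#' @return A `data.frame` of class `marker_map` with columns
#'   `snp_id`, `chrom`, `pos_bp`.
#' @export
marker_map <- function(snp_id, chrom, pos_bp) {
  snp_id <- as.character(snp_id)
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (anyDuplicated(snp_id))
    stop("marker_map: duplicated snp_id")
  if (any(is.na(pos_bp)) || any(pos_bp < 1L))
    stop("marker_map: positions must be integers >= 1")
  for (ch in unique(chrom)) {
    p <- pos_bp[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop(sprintf("marker_map: positions not strictly increasing on chromosome %s", ch))
  }
  out <- data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Genotype matrix
#'
#' Diploid dosages (copies of the alternate allele: 0, 1, 2 or `NA` for
#' missing) for a set of individuals over the markers of a [marker_map()].
#' This is the pre-phasing substrate on which quality control and the UAR
#' relationship matrix operate.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns;
#'   values restricted to 0, 1, 2, `NA`.
#' @param map a `marker_map` with one row per dosage column.
#' @param ids character vector of individual identifiers (defaults to
#'   rownames of `dosage`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map, ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(dosage)))
  ids <- as.character(ids)
  stopifnot(inherits(map, "marker_map"))
  if (ncol(dosage) != nrow(map))
    stop("genotype_matrix: dosage columns do not match map rows")
  if (length(ids) != nrow(dosage) || anyDuplicated(ids))
    stop("genotype_matrix: ids must be unique, one per row")
  bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
  if (any(bad))
    stop("genotype_matrix: dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(ids, map$snp_id)
  structure(list(dosage = dosage, map = map, ids = ids),
            class = "genotype_matrix")
}

#' Phased haplotype matrix
#'
#' Phased binary alleles for diploid individuals: two rows of `alleles` per
#' individual (rows `2i - 1` and `2i` carry individual `i`'s maternal and
#' paternal haplotypes). No missing values are permitted; phasing and
#' imputation are assumed to have happened upstream.
#'
#' @param alleles integer matrix of 0/1 values, `2 * n_individuals` rows.
#' @param map a `marker_map`.
#' @param ids individual identifiers, length `nrow(alleles) / 2`.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, map, ids = NULL) {
  alleles <- as.matrix(alleles)
  stopifnot(inherits(map, "marker_map"))
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype_matrix: allele rows must come in pairs")
  n <- nrow(alleles) %/% 2L
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n || anyDuplicated(ids))
    stop("haplotype_matrix: ids must be unique, one per individual")
  if (ncol(alleles) != nrow(map))
    stop("haplotype_matrix: allele columns do not match map rows")
  if (any(is.na(alleles)))
    stop("haplotype_matrix: missing alleles are not permitted")
  if (!all(alleles %in% c(0L, 1L)))
    stop("haplotype_matrix: alleles must be 0 or 1")
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- paste(rep(ids, each = 2L), c("a", "b"), sep = "_")
  colnames(alleles) <- map$snp_id
  structure(list(alleles = alleles, map = map, ids = ids),
            class = "haplotype_matrix")
}

#' Collapse phased haplotypes to genotype dosages
#'
#' Sums the two haplotype rows of each individual, reproducing the
#' `genotype_matrix` the haplotypes were phased from.
#'
#' @param h a `haplotype_matrix`.
#' @return A `genotype_matrix` with no missing values.
#' @export
as_genotypes <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- length(h$ids)
  a <- h$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  b <- h$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(a + b, h$map, h$ids)
}

#' Breed assignment table
#'
#' Maps every genotyped individual to exactly one breed and every breed to
#' exactly one geographic group.
#'
#' @param id individual identifiers.
#' @param breed breed code per individual.
#' @param group geographic group per individual (constant within breed).
#' @return A `data.frame` of class `breed_assignment`.
#' @export
breed_assignment <- function(id, breed, group) {
  id <- as.character(id); breed <- as.character(breed); group <- as.character(group)
  if (anyDuplicated(id))
    stop("breed_assignment: duplicated individual id")
  bg <- unique(data.frame(breed = breed, group = group, stringsAsFactors = FALSE))
  if (anyDuplicated(bg$breed))
    stop("breed_assignment: a breed maps to more than one group")
  out <- data.frame(id = id, breed = breed, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("breed_assignment", "data.frame")
  out
}

# Internal: breed codes for a vector of ids, erroring on unknowns.
breed_of <- function(breeds, ids) {
  m <- match(ids, breeds$id)
  if (anyNA(m))
    stop("individual(s) without breed assignment: ",
         paste(utils::head(ids[is.na(m)], 5L), collapse = ", "))
  breeds$breed[m]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d individuals (%d haplotypes) x %d SNPs\n",
              length(x$ids), nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}
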