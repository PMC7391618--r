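#' Read a phased VCF into a haplotype matrix
#'
#' Accepts biallelic SNP records with fully phased diploid GT fields
#' (`"|"` separator). Any unphased genotype (`"/"`) or multi-allelic record
#' aborts with an error naming the offending record, since downstream block
#' encoding requires complete phase information.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return A [haplotype_matrix()].
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("read_phased_vcf: file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("read_phased_vcf: not a readable VCF: ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi))
    stop("read_phased_vcf: multi-allelic or ALT-less record(s): ",
         paste(utils::head(fix[multi, "ID"], 5L), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(is.na(gt)))
    stop("read_phased_vcf: missing GT fields are not permitted in phased input")
  unph <- grepl("/", gt, fixed = TRUE)
  if (any(unph)) {
    w <- arrayInd(which(unph)[1L], dim(gt))
    stop(sprintf("read_phased_vcf: unphased genotype at record %s sample %s",
                 rownames(gt)[w[1L]], colnames(gt)[w[2L]]))
  }
  if (!all(grepl("^[01]\\|[01]$", gt)))
    stop("read_phased_vcf: GT fields must be phased diploid 0|0, 0|1, 1|0 or 1|1")
  ids <- colnames(gt)
  snp_id <- fix[, "ID"]
  if (any(is.na(snp_id)) || any(snp_id == "."))
    snp_id <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  map <- marker_map(snp_id, fix[, "CHROM"], as.integer(fix[, "POS"]))
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  alleles <- matrix(0L, nrow = 2L * length(ids), ncol = nrow(map))
  alleles[seq(1L, by = 2L, length.out = length(ids)), ] <- t(a1)
  alleles[seq(2L, by = 2L, length.out = length(ids)), ] <- t(a2)
  haplotype_matrix(alleles, map, ids)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields; `read_phased_vcf()` on the
#' result round-trips the alleles exactly.
#'
#' @param h a `haplotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- length(h$ids)
  a1 <- h$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- h$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(t(a1), "|", t(a2)), nrow = ncol(a1))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", h$ids), collapse = "\t"))
  body <- paste(h$map$chrom, h$map$pos_bp, h$map$snp_id, "A", "G", ".", "PASS",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Whitespace-delimited PED with the usual six leading columns and two allele
#' columns per SNP; `"0"` marks a missing allele. PED files carry no
#' reference/alternate designation, so for each SNP the alternate allele is
#' taken as the lexicographically larger of the observed alleles - an
#' arbitrary but deterministic convention.
#'
#' @param ped,map paths to the PED and MAP files.
#' @return A [genotype_matrix()] (dosages count alternate-allele copies).
#' @export
read_plink_text <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("read_plink_text: MAP needs 4 columns")
  mmap <- marker_map(mp[[2L]], mp[[1L]], mp[[4L]])
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  m <- nrow(mmap)
  if (ncol(pd) != 6L + 2L * m)
    stop(sprintf("read_plink_text: PED has %d columns, expected %d for %d SNPs",
                 ncol(pd), 6L + 2L * m, m))
  ids <- pd[[2L]]
  al <- as.matrix(pd[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  dosage <- matrix(NA_real_, nrow = nrow(pd), ncol = m)
  for (k in seq_len(m)) {
    obs <- c(a1[, k], a2[, k])
    obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2L)
      stop(sprintf("read_plink_text: SNP %s has >2 alleles", mmap$snp_id[k]))
    if (length(obs) == 0L) next  # all missing; dosage stays NA
    altallele <- obs[length(obs)]  # lexicographically larger observed allele
    miss <- a1[, k] == "0" | a2[, k] == "0"
    dosage[, k] <- (a1[, k] == altallele) + (a2[, k] == altallele)
    dosage[miss, k] <- NA_real_
  }
  genotype_matrix(dosage, mmap, ids)
}

#' Read a breed/group assignment TSV
#'
#' Expects a header line and columns `individual`, `breed`, `group`.
#' When `genotyped_ids` is supplied, genotyped individuals absent from the
#' table are reported with a warning and returned in the `excluded`
#' attribute so callers can drop them.
#'
#' @param path path to the TSV.
#' @param genotyped_ids optional character vector of genotyped individuals.
#' @return A [breed_assignment()]; attribute `excluded` lists genotyped
#'   individuals without an assignment.
#' @export
read_breed_map <- function(path, genotyped_ids = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("individual", "breed", "group")
  if (!all(need %in% names(tb)))
    stop("read_breed_map: columns must include individual, breed, group")
  if (anyDuplicated(tb$individual))
    stop("read_breed_map: duplicated individual: ",
         tb$individual[duplicated(tb$individual)][1L])
  out <- breed_assignment(tb$individual, tb$breed, tb$group)
  excluded <- character(0)
  if (!is.null(genotyped_ids)) {
    excluded <- setdiff(genotyped_ids, out$id)
    if (length(excluded))
      warning("read_breed_map: ", length(excluded),
              " genotyped individual(s) lack a breed assignment")
  }
  attr(out, "excluded") <- excluded
  out
}

#' Packaged reference table of per-breed diversity statistics
#'
#' Loads the transcribed 115-breed reference table (Nd, nA, mA, H_O, H_E,
#' H_def, npA, nspA, fpA, F, AR, SNP-based heterozygosities and the
#' LD-based Ne at 5, 50 and 2000 generations) that anchors the package's
#' reported group summaries and correlations. The file is shipped with an
#' integrity checksum; a mismatch indicates a corrupted installation.
#'
#' Dataset-level counts that do not live in any per-breed row (number of
#' blocks and SNPs, total and common allele counts over all breeds) are
#' returned as attributes.
#'
#' @return A `data.frame`, one row per breed, with attributes `n_blocks`,
#'   `n_snps`, `n_individuals_total`, `n_individuals_retained`,
#'   `total_distinct_alleles`, `common_alleles`.
#' @export
load_reference_table <- function() {
  path <- system.file("extdata", "breed_reference_table.tsv",
                      package = "herddiv", mustWork = TRUE)
  sum_seen <- unname(tools::md5sum(path))
  if (!identical(sum_seen, .reference_table_md5))
    stop("load_reference_table: fixture checksum mismatch (corrupted install?)")
  hdr <- readLines(path, n = 20L)
  meta_lines <- grep("^# [a-z_]+=", hdr, value = TRUE)
  tb <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(tb) != 115L)
    stop("load_reference_table: expected 115 breeds, found ", nrow(tb))
  for (ml in meta_lines) {
    kv <- strsplit(sub("^# ", "", ml), "=", fixed = TRUE)[[1L]]
    attr(tb, kv[1L]) <- as.numeric(kv[2L])
  }
  tb
}

.reference_table_md5 <- "4123cc702684159a83fb0d7aa20a8b61"

#' Breed assignment derived from the reference table
#'
#' Convenience wrapper mapping each reference-table breed to its geographic
#' group, for use with the group-summary functions.
#'
#' @param ref a reference table from [load_reference_table()].
#' @return A [breed_assignment()] with one pseudo-individual per breed.
#' @export
reference_breed_groups <- function(ref = load_reference_table()) {
  breed_assignment(ref$breed, ref$breed, ref$group)
}
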