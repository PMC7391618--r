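# brute-force diversity oracle from raw block genotypes
diversity_oracle <- function(bg, breeds) {
  br <- breeds$breed[match(bg$ids, breeds$id)]
  out <- list()
  for (b in sort(unique(br))) {
    sel <- br == b
    N <- sum(sel)
    nA <- 0; he <- c(); ho <- c()
    for (j in seq_len(ncol(bg$a1))) {
      words <- c(bg$a1[sel, j], bg$a2[sel, j])
      nA <- nA + length(unique(words))
      p <- table(words) / length(words)
      he <- c(he, (2 * N / (2 * N - 1)) * (1 - sum(p^2)))
      ho <- c(ho, mean(bg$a1[sel, j] != bg$a2[sel, j]))
    }
    out[[b]] <- c(nA = nA, H_O = mean(ho), H_E = mean(he))
  }
  out
}

random_block_genotypes <- function(n_ind = 12, n_snps = 24, seed = 1,
                                   n_breeds = 3) {
  set.seed(seed)
  al <- matrix(rbinom(2 * n_ind * n_snps, 1, 0.5), nrow = 2 * n_ind)
  h <- toy_haplotypes(al, ids = sprintf("i%02d", 1:n_ind))
  bl <- build_blocks(h$map)
  bg <- encode_block_alleles(h, bl)
  br <- breed_assignment(h$ids,
                         sprintf("B%d", rep_len(seq_len(n_breeds), n_ind)),
                         rep("G", n_ind))
  list(bg = bg, br = br)
}

test_that("allele counts conserve gene copies and reject unassigned animals", {
  x <- random_block_genotypes(seed = 2)
  tab <- breed_allele_counts(x$bg, x$br)
  for (j in seq_along(tab$counts))
    expect_equal(colSums(tab$counts[[j]]), tab$copies[colnames(tab$counts[[j]])])
  br_bad <- breed_assignment("someone_else", "B1", "G")
  expect_error(breed_allele_counts(x$bg, br_bad), "without breed")
})

test_that("diversity summary equals the brute-force tally oracle", {
  x <- random_block_genotypes(seed = 3)
  tab <- breed_allele_counts(x$bg, x$br)
  ds <- diversity_summary(tab)
  orc <- diversity_oracle(x$bg, x$br)
  for (i in seq_len(nrow(ds))) {
    o <- orc[[ds$breed[i]]]
    expect_equal(ds$nA[i], unname(o["nA"]))
    expect_equal(ds$H_O[i], unname(o["H_O"]))
    expect_equal(ds$H_E[i], unname(o["H_E"]))
    expect_equal(ds$mA[i], ds$nA[i] / length(tab$counts))
    expect_equal(ds$H_def[i], (ds$H_E[i] - ds$H_O[i]) / ds$H_E[i])
  }
})

test_that("diversity summary is equivariant under breed relabeling", {
  x <- random_block_genotypes(seed = 4)
  tab <- breed_allele_counts(x$bg, x$br)
  ds <- diversity_summary(tab)
  br2 <- x$br
  relabel <- c(B1 = "Z9", B2 = "A0", B3 = "M5")
  br2$breed <- unname(relabel[br2$breed])
  ds2 <- diversity_summary(breed_allele_counts(x$bg, br2))
  for (b in names(relabel)) {
    i <- ds$breed == b; i2 <- ds2$breed == relabel[[b]]
    expect_equal(ds2$H_E[i2], ds$H_E[i])
    expect_equal(ds2$nA[i2], ds$nA[i])
  }
})

test_that("fully heterozygous single block approaches the H_def = -1 limit", {
  N <- 50
  a1 <- matrix("0011", N, 1); a2 <- matrix("1100", N, 1)
  bg <- structure(list(a1 = a1, a2 = a2, ids = sprintf("i%02d", 1:N),
                       blocks = NULL), class = "block_genotypes")
  rownames(bg$a1) <- rownames(bg$a2) <- bg$ids
  colnames(bg$a1) <- colnames(bg$a2) <- "blk1"
  tab <- breed_allele_counts(bg, one_breed(bg$ids))
  ds <- diversity_summary(tab)
  expect_equal(ds$H_O, 1)
  expect_equal(ds$H_E, 0.5, tolerance = 0.02)
  expect_lt(ds$H_def, -0.9)
})

test_that("rarefaction reproduces hand-computed allelic richness", {
  cm1 <- matrix(c(4, 4), 2, 1, dimnames = list(c("a", "b"), "B1"))
  tab1 <- manual_allele_table(list(cm1))
  expect_equal(unname(allelic_richness(tab1, 8)), 2)  # full depth

  cm2 <- matrix(c(7, 1), 2, 1, dimnames = list(c("a", "b"), "B1"))
  tab2 <- manual_allele_table(list(cm2))
  expect_equal(unname(allelic_richness(tab2, 2)), 1.25)  # 1 + (1 - 21/28)

  expect_error(allelic_richness(tab2, 9), "exceeds")
})

test_that("allelic richness is monotone non-decreasing in g", {
  set.seed(6)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    cm <- matrix(rmultinom(1, 20, rep(1 / k, k)), ncol = 1,
                 dimnames = list(paste0("w", 1:k), "B1"))
    tab <- manual_allele_table(list(cm))
    ar <- sapply(1:20, function(g) allelic_richness(tab, g))
    expect_true(all(diff(ar) > -1e-12))
    expect_equal(unname(ar[20]), sum(cm > 0))
  }
})

test_that("private-allele bookkeeping matches an occupancy oracle", {
  # two breeds sharing every allele
  cm <- matrix(c(3, 5, 5, 3), 2, 2, dimnames = list(c("x", "y"), c("A", "B")))
  tab <- manual_allele_table(list(cm))
  pv <- private_allele_counts(tab)
  expect_equal(unname(pv$npA), c(0L, 0L))
  expect_equal(pv$ncA, 2L)

  # single private allele at frequency 0.3 in breed A
  cmA <- matrix(c(3, 7, 0, 10), 2, 2, dimnames = list(c("priv", "shr"), c("A", "B")))
  tabA <- manual_allele_table(list(cmA))
  pvA <- private_allele_counts(tabA)
  expect_equal(unname(pvA$npA["A"]), 1L)
  expect_equal(unname(pvA$fpA["A"]), 0.3)

  # random 3-breed table vs brute-force occupancy
  set.seed(7)
  x <- random_block_genotypes(seed = 7)
  tab3 <- breed_allele_counts(x$bg, x$br)
  pv3 <- private_allele_counts(tab3)
  npA_o <- nspA_o <- stats::setNames(rep(0L, 3), tab3$breeds); ncA_o <- 0L
  for (j in seq_along(tab3$counts)) {
    cmj <- tab3$counts[[j]]
    for (u in rownames(cmj)) {
      occ <- names(which(cmj[u, ] > 0))
      if (length(occ) == 1) npA_o[occ] <- npA_o[occ] + 1L
      if (length(occ) == 2) nspA_o[occ] <- nspA_o[occ] + 1L
      if (length(occ) == 3) ncA_o <- ncA_o + 1L
    }
  }
  expect_equal(pv3$npA, npA_o)
  expect_equal(pv3$nspA, nspA_o)
  expect_equal(pv3$ncA, ncA_o)
  # every occupancy-2 allele credited twice
  expect_equal(sum(pv3$nspA) %% 2, 0)
})

test_that("SNP heterozygosity matches the block estimator on 1-SNP blocks", {
  # all-heterozygote and fixed breeds
  g <- toy_genotypes(matrix(1, 5, 4), ids = paste0("h", 1:5))
  sh <- snp_heterozygosity(g, one_breed(g$ids))
  expect_equal(sh$H_O_snp, 1)
  g0 <- toy_genotypes(matrix(2, 5, 4), ids = paste0("f", 1:5))
  sh0 <- snp_heterozygosity(g0, one_breed(g0$ids))
  expect_equal(sh0$H_O_snp, 0)
  expect_equal(sh0$H_E_snp, 0)

  # equivalence with the multi-allelic machinery on single-SNP blocks
  set.seed(10)
  al <- matrix(rbinom(16 * 6, 1, 0.4), nrow = 16)
  h <- toy_haplotypes(al, ids = sprintf("i%02d", 1:8))
  br <- breed_assignment(h$ids, rep(c("A", "B"), each = 4), rep("G", 8))
  blocks1 <- data.frame(block_id = paste0("b", 1:6),
                        chrom = h$map$chrom, start_bp = h$map$pos_bp,
                        end_bp = h$map$pos_bp, stringsAsFactors = FALSE)
  blocks1$snp_index <- matrix(1:6, ncol = 1)
  class(blocks1) <- c("block_definition", "data.frame")
  bg1 <- encode_block_alleles(h, blocks1)
  ds1 <- diversity_summary(breed_allele_counts(bg1, br))
  shs <- snp_heterozygosity(as_genotypes(h), br)
  expect_equal(ds1$H_O, shs$H_O_snp)
  expect_equal(ds1$H_E, shs$H_E_snp)
})

test_that("group summaries and correlations reproduce the reference table", {
  ref <- load_reference_table()
  grp <- reference_breed_groups(ref)
  gs <- group_weighted_summary(ref, grp, stats = c("F", "AR", "H_O", "H_E"))
  gc <- gs[gs$group == "GreeceCyprus", ]
  expect_equal(gc$F, 0.178, tolerance = 0.005)
  expect_equal(gc$AR, 3.54, tolerance = 0.005)
  expect_equal(gc$H_O, 0.656, tolerance = 0.005)
  expect_equal(gc$H_E, 0.641, tolerance = 0.005)

  # single-breed group equals the breed value
  one <- ref[ref$breed == "GRB", ]
  gs1 <- group_weighted_summary(one, breed_assignment("GRB", "GRB", "solo"),
                                stats = "F")
  expect_equal(gs1$F, one$F)

  r <- correlate_f_private(ref, exclude_groups = "Outgroup")
  expect_lt(abs(r[["r_F_fpA"]] - 0.72), 0.005)   # printed to 2 d.p.
  expect_lt(abs(r[["r_F_npA"]] + 0.21), 0.005)

  # degenerate perfect-correlation case
  toy <- data.frame(F = c(.1, .2, .3), fpA = c(.1, .2, .3), npA = c(5, 4, 3))
  expect_equal(unname(correlate_f_private(toy)["r_F_fpA"]), 1)
})
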