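# independent straight-line D computation from two count vectors
dest_oracle <- function(counts_list, a, b, copies) {
  Na <- copies[[a]] / 2; Nb <- copies[[b]] / 2
  Nh <- 2 / (1 / Na + 1 / Nb)
  hs <- ht <- numeric(length(counts_list))
  for (j in seq_along(counts_list)) {
    pa <- counts_list[[j]][, a] / copies[[a]]
    pb <- counts_list[[j]][, b] / copies[[b]]
    hs[j] <- (2 * Nh / (2 * Nh - 1)) * (1 - (sum(pa^2) + sum(pb^2)) / 2)
    ht[j] <- 1 - sum(((pa + pb) / 2)^2) + hs[j] / (4 * Nh)
  }
  HS <- mean(hs); HT <- mean(ht)
  max(0, min(1, 2 * (HT - HS) / (1 - HS)))
}

test_that("Jost's D hits its trivial anchors", {
  # identical frequency tables, large equal samples -> ~0
  cm <- matrix(c(40, 60, 40, 60), 2, 2, dimnames = list(c("x", "y"), c("A", "B")))
  tab <- manual_allele_table(list(cm, cm))
  expect_lt(dest_pairwise(tab, "A", "B"), 0.01)
  # fixed for different alleles everywhere -> 1
  cm2 <- matrix(c(20, 0, 0, 20), 2, 2, dimnames = list(c("x", "y"), c("A", "B")))
  tab2 <- manual_allele_table(list(cm2, cm2))
  expect_equal(dest_pairwise(tab2, "A", "B"), 1)
})

test_that("Jost's D equals an independently coded oracle", {
  set.seed(12)
  for (rep in 1:5) {
    counts <- lapply(1:6, function(j) {
      k <- sample(2:5, 1)
      m <- cbind(A = rmultinom(1, 24, rep(1, k))[, 1],
                 B = rmultinom(1, 36, rep(1, k))[, 1])
      rownames(m) <- paste0("w", 1:k)
      m
    })
    tab <- manual_allele_table(counts)
    expect_equal(dest_pairwise(tab, "A", "B"),
                 dest_oracle(counts, "A", "B", tab$copies),
                 tolerance = 1e-12)
    # symmetry and label invariance
    expect_equal(dest_pairwise(tab, "A", "B"), dest_pairwise(tab, "B", "A"))
  }
})

test_that("D_EST summaries aggregate pair sets correctly", {
  m <- matrix(c(0, .1, .4,
                .1, 0, .3,
                .4, .3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  class(m) <- c("dest_matrix", class(m))
  br <- breed_assignment(c("A", "B", "C"), c("A", "B", "C"),
                         c("g1", "g1", "g2"))
  s <- dest_summaries(m, br)
  expect_equal(unname(s$per_breed["A"]), mean(c(.1, .4)))
  expect_equal(unname(s$within_group["g1"]), .1)
  expect_true(is.na(s$within_group["g2"]))   # single-breed group

  m0 <- m; m0[] <- 0
  class(m0) <- c("dest_matrix", class(m0))
  expect_true(all(dest_summaries(m0, br)$per_breed == 0))
})

test_that("allele-sharing distance counts multiset intersections", {
  a1 <- rbind(c("0000"), c("0000"), c("1111"), c("0011"), c("0011"))
  a2 <- rbind(c("0000"), c("0000"), c("1111"), c("1100"), c("0000"))
  ids <- c("homA", "homA2", "homB", "het", "mix")
  bg <- structure(list(a1 = matrix(a1, 5, 1, dimnames = list(ids, "b1")),
                       a2 = matrix(a2, 5, 1, dimnames = list(ids, "b1")),
                       ids = ids, blocks = NULL), class = "block_genotypes")
  d <- allele_sharing_distance(bg)
  expect_equal(d["homA", "homA2"], 0)     # identical homozygotes
  expect_equal(d["homA", "homB"], 1)      # disjoint homozygotes
  expect_equal(d["het", "mix"], 0.5)      # one shared allele
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, 5))
})

test_that("mean within-breed D_PS averages distinct pairs", {
  set.seed(13)
  al <- matrix(rbinom(12 * 8, 1, 0.5), nrow = 12)
  h <- toy_haplotypes(al, ids = sprintf("i%02d", 1:6))
  bg <- encode_block_alleles(h, build_blocks(h$map))
  d <- allele_sharing_distance(bg)
  br <- breed_assignment(h$ids, rep(c("A", "B", "C"), c(3, 2, 1)), rep("G", 6))
  mw <- mean_within_breed_dps(d, br)
  sel <- h$ids[1:3]
  expect_equal(unname(mw["A"]),
               mean(c(d[sel[1], sel[2]], d[sel[1], sel[3]], d[sel[2], sel[3]])))
  expect_equal(unname(mw["B"]), d[h$ids[4], h$ids[5]])
  expect_true(is.na(mw["C"]))
  # clones at distance zero
  bgc <- bg; bgc$a1[] <- "0000"; bgc$a2[] <- "0000"
  dc <- allele_sharing_distance(bgc)
  expect_equal(unname(mean_within_breed_dps(dc, br)["A"]), 0)
})

test_that("classical MDS reconstructs Euclidean configurations", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(2, 2))
  d <- as.matrix(dist(pts))
  xy <- classical_mds(d, 2)
  expect_equal(as.matrix(dist(xy)), d, tolerance = 1e-8, ignore_attr = TRUE)

  # equilateral: all pairwise distances equal after embedding
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  xy3 <- classical_mds(d3, 2)
  dd <- as.matrix(dist(xy3))
  expect_equal(max(dd[upper.tri(dd)]) - min(dd[upper.tri(dd)]), 0,
               tolerance = 1e-10)

  # duplicated individuals land on the same point
  pts2 <- rbind(pts, pts[1, ])
  d5 <- as.matrix(dist(pts2))
  xy5 <- classical_mds(d5, 2)
  expect_equal(xy5[5, ], xy5[1, ], tolerance = 1e-10)

  # deterministic sign convention
  expect_equal(classical_mds(d, 2), xy)
})

test_that("breed dispersion radius is the SD of member-center distances", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  rownames(sq) <- paste0("i", 1:4)
  br <- one_breed(rownames(sq), "SQ")
  bd <- breed_dispersion(sq, br)
  expect_equal(bd$x, 0.5); expect_equal(bd$y, 0.5)
  expect_equal(bd$radius, 0)           # all distances sqrt(0.5)

  single <- matrix(c(2, 3), 1, 2, dimnames = list("solo", NULL))
  bd1 <- breed_dispersion(single, one_breed("solo", "S"))
  expect_equal(bd1$radius, 0)
})

test_that("D_EST increases with the generator's divergence parameter", {
  fst_grid <- c(0.02, 0.06, 0.12, 0.20)
  reps <- 5
  dmat <- sapply(seq_along(fst_grid), function(k) {
    sapply(1:reps, function(r) {
      sim <- simulate_hierarchical(2, 15, 240, fst = fst_grid[k],
                                   seed = 1000 * k + r)
      bg <- encode_block_alleles(sim$haplotypes, build_blocks(sim$haplotypes$map))
      tab <- breed_allele_counts(bg, sim$breeds)
      dest_pairwise(tab, "POP01", "POP02")
    })
  })
  means <- colMeans(dmat)
  expect_true(all(diff(means) > 0))
  expect_gt(cor(rep(fst_grid, each = reps), as.vector(dmat),
                method = "spearman"), 0.9)
})
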