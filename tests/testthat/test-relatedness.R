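# brute-force UAR oracle: literal double loop over the published formulas
uar_oracle <- function(x, p) {
  n <- nrow(x); m <- ncol(x)
  u <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) {
      u[i, i] <- 1 + mean(sapply(1:m, function(k)
        (x[i, k]^2 - (1 + 2 * p[k]) * x[i, k] + 2 * p[k]^2) /
          (2 * p[k] * (1 - p[k]))))
    } else {
      u[i, j] <- mean(sapply(1:m, function(k)
        (x[i, k] - 2 * p[k]) * (x[j, k] - 2 * p[k]) /
          (2 * p[k] * (1 - p[k]))))
    }
  }
  u
}

test_that("allele frequencies are sane and guard against fixation", {
  g <- toy_genotypes(matrix(c(0, 1, 2), ncol = 1))
  expect_equal(unname(allele_frequencies(g)), 0.5)
  g2 <- toy_genotypes(matrix(c(2, 2), ncol = 1))
  expect_error(allele_frequencies(g2), "monomorphic")
  set.seed(3)
  g3 <- toy_genotypes(matrix(rbinom(100, 2, 0.3), ncol = 1))
  phat <- unname(allele_frequencies(g3))
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / 200))  # binomial CI
})

test_that("UAR diagonal reproduces hand-computed single-SNP values", {
  # homozygous alt at p = 0.5: (4 - 4 + 0.5)/0.5 = 1 -> UAR = 2, F = 1
  g <- toy_genotypes(matrix(c(2, 0), ncol = 1), ids = c("hom", "ref"))
  u <- uar_matrix(g, p = 0.5)
  expect_equal(unname(diag(u)[1]), 2)
  expect_equal(unname(inbreeding_from_uar(u)[1]), 1)
  # heterozygote at p = 0.5: (1 - 2 + 0.5)/0.5 = -1 -> UAR = 0, F = -1
  g2 <- toy_genotypes(matrix(c(1, 1), ncol = 1), ids = c("h1", "h2"))
  u2 <- uar_matrix(g2, p = 0.5)
  expect_equal(unname(diag(u2)), c(0, 0))
  expect_equal(unname(inbreeding_from_uar(u2)), c(-1, -1))
})

test_that("UAR equals the brute-force pair-loop oracle", {
  set.seed(11)
  x <- matrix(rbinom(20 * 50, 2, runif(50, 0.2, 0.8)), 20, 50, byrow = FALSE)
  x[, 1] <- c(rep(1, 10), rep(0, 5), rep(2, 5))  # keep polymorphic
  g <- toy_genotypes(x, ids = sprintf("i%02d", 1:20))
  p <- allele_frequencies(g)
  u <- uar_matrix(g, p)
  expect_equal(unname(unclass(u)), uar_oracle(x, p), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(u)))
  # two identical individuals have identical rows
  x2 <- rbind(x, x[1, ])
  g2 <- toy_genotypes(x2, ids = c(sprintf("i%02d", 1:20), "dup"))
  u2 <- uar_matrix(g2, p)
  # identical rows agree on all partner columns (self entries use the
  # diagonal formula and are compared separately)
  expect_equal(unname(u2["dup", -c(1, 21)]), unname(u2["i01", -c(1, 21)]))
  expect_equal(u2["dup", "dup"], u2["i01", "i01"])
})

test_that("mean off-diagonal UAR vanishes under Hardy-Weinberg sampling", {
  set.seed(21)
  p <- runif(10000, 0.1, 0.9)
  x <- matrix(rbinom(15 * 10000, 2, rep(p, each = 15)), nrow = 15)
  g <- toy_genotypes(x, ids = sprintf("i%02d", 1:15))
  u <- unclass(uar_matrix(g, p))
  expect_lt(abs(mean(u[upper.tri(u)])), 0.01)
})

test_that("generator inbreeding is recovered from the UAR diagonal", {
  sim <- simulate_hierarchical(1, 40, 2000, fst = 0, inbreeding = 0.25, seed = 31)
  g <- filter_maf(as_genotypes(sim$haplotypes), 0.01)$genotypes
  u <- uar_matrix(g)
  expect_lt(abs(mean(inbreeding_from_uar(u)) - 0.25), 0.05)
})

test_that("a migrant individual is flagged as multivariate outlier", {
  sim <- simulate_hierarchical(2, c(20, 20), 800, fst = c(0.25, 0.25), seed = 41)
  g <- filter_maf(as_genotypes(sim$haplotypes), 0.01)$genotypes
  u <- uar_matrix(g)
  # mislabel one POP02 animal as POP01
  br <- sim$breeds
  migrant <- br$id[br$breed == "POP02"][1]
  br$breed[br$id == migrant] <- "POP01"
  fl <- detect_outliers(u, br)
  expect_true(fl[[migrant]])   # flagged within its claimed breed
})

test_that("tiny breeds are skipped by the outlier test", {
  sim <- simulate_hierarchical(1, 4, 200, fst = 0, seed = 5)
  g <- filter_maf(as_genotypes(sim$haplotypes), 0.01)$genotypes
  u <- uar_matrix(g)
  fl <- detect_outliers(u, sim$breeds)
  expect_false(any(fl))
  expect_equal(attr(fl, "skipped"), "POP01")
})

test_that("greedy pruning removes the most-connected individual first", {
  ids <- c("dam", "off", "sire")
  u <- matrix(c(1, .5, 0,
                .5, 1, .5,
                0, .5, 1), 3, 3, dimnames = list(ids, ids))
  class(u) <- c("uar_matrix", class(u))
  br <- one_breed(ids)
  pr <- prune_related(u, br, threshold = 0.45)
  expect_equal(pr$removed$id, "off")        # 2 partners vs 1 each
  expect_equal(sort(pr$kept), c("dam", "sire"))

  # unrelated set untouched
  u2 <- diag(3); dimnames(u2) <- list(ids, ids)
  class(u2) <- c("uar_matrix", class(u2))
  pr2 <- prune_related(u2, br)
  expect_equal(nrow(pr2$removed), 0L)
  expect_equal(sort(pr2$kept), sort(ids))
})

test_that("pruning post-condition: no kept within-breed pair above threshold", {
  set.seed(51)
  n <- 25
  u <- matrix(runif(n * n, 0, 0.6), n, n)
  u <- (u + t(u)) / 2; diag(u) <- 1
  ids <- sprintf("i%02d", 1:n)
  dimnames(u) <- list(ids, ids)
  class(u) <- c("uar_matrix", class(u))
  br <- breed_assignment(ids, rep(c("A", "B"), length.out = n), rep("G", n))
  pr <- prune_related(u, br, threshold = 0.45)
  kept <- pr$kept
  brk <- br$breed[match(kept, br$id)]
  for (b in unique(brk)) {
    sel <- kept[brk == b]
    if (length(sel) > 1) {
      sub <- u[sel, sel]; diag(sub) <- 0
      expect_lte(max(sub), 0.45)
    }
  }
  expect_setequal(c(pr$kept, pr$removed$id), ids)
})
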