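#' Hierarchical multi-breed genotype simulator
#'
#' Balding-Nichols drift model standing in for a multi-breed SNP-array
#' cohort: ancestral frequencies are drawn Uniform(0.05, 0.95) (mimicking
#' array ascertainment against rare variants), each population's
#' frequencies are Beta-distributed around them with its divergence
#' parameter `fst`, admixed populations mix the frequencies of their
#' sources, and within an individual the two gene copies are drawn with
#' correlation equal to the population's inbreeding parameter (the second
#' copy repeats the first with probability `inbreeding`). Markers sit on a
#' uniformly spaced map so haplotype blocks can form. Note the sites are
#' exchangeable (no LD beyond inbreeding); use
#' [simulate_wright_fisher()] when LD structure matters.
#'
#' @param n_pops number of populations (breeds).
#' @param n_per_pop breed sizes, recycled to `n_pops`.
#' @param n_snps number of SNPs.
#' @param fst per-population divergence in (0, 1); 0 means no drift.
#' @param admixture optional `n_pops x n_pops` row-stochastic matrix;
#'   population i's frequencies are `sum_j admixture[i,j] * p_j` of the
#'   drifted source frequencies.
#' @param inbreeding per-population within-individual allele correlation.
#' @param groups optional group label per population (defaults to one
#'   group).
#' @param map_spacing_bp distance between adjacent markers (default
#'   10 kb); a chromosome break is inserted every `snps_per_chrom` SNPs.
#' @param snps_per_chrom markers per chromosome (default 1000).
#' @param seed RNG seed; all randomness flows from it.
#' @return List with `haplotypes` (a `haplotype_matrix`), `breeds`
#'   (a `breed_assignment`) and `truth` (the generator parameters,
#'   including the realised per-population frequencies).
#' @export
simulate_hierarchical <- function(n_pops, n_per_pop, n_snps, fst,
                                  admixture = NULL, inbreeding = 0,
                                  groups = NULL, map_spacing_bp = 10000L,
                                  snps_per_chrom = 1000L, seed = 1L) {
  set.seed(seed)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst <- rep_len(fst, n_pops)
  inbreeding <- rep_len(inbreeding, n_pops)
  stopifnot(all(fst >= 0), all(fst < 1),
            all(inbreeding >= 0), all(inbreeding <= 1))
  if (is.null(groups)) groups <- rep("G1", n_pops)
  p_anc <- stats::runif(n_snps, 0.05, 0.95)
  p_pop <- matrix(0, n_pops, n_snps)
  for (b in seq_len(n_pops)) {
    p_pop[b, ] <- if (fst[b] == 0) p_anc else
      stats::rbeta(n_snps, p_anc * (1 - fst[b]) / fst[b],
                   (1 - p_anc) * (1 - fst[b]) / fst[b])
  }
  if (!is.null(admixture)) {
    stopifnot(nrow(admixture) == n_pops, ncol(admixture) == n_pops,
              all(abs(rowSums(admixture) - 1) < 1e-8))
    p_pop <- admixture %*% p_pop
  }
  # clamp away exact fixation so downstream frequency math stays finite
  p_pop <- pmin(pmax(p_pop, 1e-6), 1 - 1e-6)
  n_tot <- sum(n_per_pop)
  alleles <- matrix(0L, 2L * n_tot, n_snps)
  pop_of <- rep(seq_len(n_pops), n_per_pop)
  for (i in seq_len(n_tot)) {
    b <- pop_of[i]
    a1 <- stats::rbinom(n_snps, 1L, p_pop[b, ])
    copy <- stats::runif(n_snps) < inbreeding[b]
    a2 <- ifelse(copy, a1, stats::rbinom(n_snps, 1L, p_pop[b, ]))
    alleles[2L * i - 1L, ] <- a1
    alleles[2L * i, ] <- as.integer(a2)
  }
  chrom <- rep(seq_len(ceiling(n_snps / snps_per_chrom)),
               each = snps_per_chrom)[seq_len(n_snps)]
  within <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along)
  map <- marker_map(sprintf("snp%05d", seq_len(n_snps)), chrom,
                    1L + (within - 1L) * map_spacing_bp)
  ids <- sprintf("P%02d_i%03d", pop_of, stats::ave(pop_of, pop_of, FUN = seq_along))
  h <- haplotype_matrix(alleles, map, ids)
  breeds <- breed_assignment(ids, sprintf("POP%02d", pop_of),
                             groups[pop_of])
  truth <- list(seed = seed, p_anc = p_anc, p_pop = p_pop, fst = fst,
                admixture = admixture, inbreeding = inbreeding,
                n_per_pop = n_per_pop)
  list(haplotypes = h, breeds = breeds, truth = truth)
}

#' Forward Wright-Fisher simulator with recombination
#'
#' Discrete-generation forward simulation of `2 * ne` haplotypes on one
#' chromosome: each offspring haplotype is a recombinant of the two
#' haplotypes of a random parent, with Poisson crossovers at the stated
#' genetic rate. Initial frequencies are Uniform(0.05, 0.95)-drawn
#' independent sites; after the burn-in the LD pattern reflects the
#' constant population size, which is what the LD-based Ne estimator is
#' meant to recover. Sites fixed at output are dropped.
#'
#' @param ne constant diploid population size (>= 10).
#' @param generations generations simulated (>= 4 * ne recommended).
#' @param n_snps sites placed uniformly along the chromosome.
#' @param chrom_length_bp chromosome length (default 50 Mb).
#' @param recomb_rate cM/Mb (default 1).
#' @param n_sample diploids sampled at the end (default `ne`).
#' @param seed RNG seed.
#' @return List with `haplotypes` (the sample, polymorphic sites only)
#'   and `truth` (`ne`, `generations`, parameters, surviving site count).
#' @export
simulate_wright_fisher <- function(ne, generations, n_snps,
                                   chrom_length_bp = 5e7, recomb_rate = 1.0,
                                   n_sample = ne, seed = 1L) {
  stopifnot(ne >= 10, n_sample <= ne)
  set.seed(seed)
  pos <- sort(sample.int(chrom_length_bp - 1L, n_snps)) + 0L
  nh <- 2L * ne
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  pop <- matrix(stats::rbinom(nh * n_snps, 1L, rep(p0, each = nh)), nrow = nh)
  morgans <- chrom_length_bp * recomb_rate * 1e-8
  frac <- pos / chrom_length_bp
  for (gen in seq_len(generations)) {
    parent <- sample.int(ne, nh, replace = TRUE)
    r1 <- 2L * parent - 1L
    nco <- stats::rpois(nh, morgans)
    start <- stats::runif(nh) < 0.5
    newpop <- matrix(0L, nh, n_snps)
    simple <- nco == 0L
    if (any(simple))
      newpop[simple, ] <- pop[r1[simple] + !start[simple], , drop = FALSE]
    for (k in which(!simple)) {
      bp <- sort(stats::runif(nco[k]))
      strand <- (findInterval(frac, bp) + start[k]) %% 2L  # 0 -> first strand
      hap <- pop[r1[k], ]
      other <- pop[r1[k] + 1L, ]
      hap[strand == 1L] <- other[strand == 1L]
      newpop[k, ] <- hap
    }
    pop <- newpop
  }
  sel <- sample.int(ne, n_sample)
  rows <- as.vector(rbind(2L * sel - 1L, 2L * sel))
  out <- pop[rows, , drop = FALSE]
  poly <- colSums(out) > 0L & colSums(out) < nrow(out)
  if (!any(poly))
    stop("simulate_wright_fisher: all sites fixed; increase n_snps or reduce generations")
  out <- out[, poly, drop = FALSE]
  map <- marker_map(sprintf("wf%05d", which(poly)), "1", pos[poly])
  h <- haplotype_matrix(out, map, sprintf("wf_i%03d", seq_len(n_sample)))
  truth <- list(seed = seed, ne = ne, generations = generations,
                recomb_rate = recomb_rate, chrom_length_bp = chrom_length_bp,
                n_polymorphic = sum(poly))
  list(haplotypes = h, truth = truth)
}

#' Frequency simulator for the four-population D-statistic design
#'
#' Evolves allele frequencies along (((P1,P2),P3),O) by Balding-Nichols
#' drift with per-branch drift amounts, then replaces a fraction of P2's
#' site frequencies with P3's (post-split introgression). With
#' `introgression_fraction = 0` the design is a clean tree and D has mean
#' zero; positive fractions push D (and Z) positive.
#'
#' @param n_snps number of sites.
#' @param drift per-branch drift parameters, named vector with elements
#'   `root_internal` (ancestor to the (P1,P2,P3) ancestor), `internal_p12`
#'   (to the (P1,P2) ancestor), `p1`, `p2`, `p3`, `outgroup`.
#' @param introgression_fraction fraction of P2 sites copied from P3.
#' @param seed RNG seed.
#' @param pos_bp optional site positions (default 5 kb spacing).
#' @return List with frequency vectors `p1`, `p2`, `p3`, `pO`, positions
#'   `pos_bp`, and `truth`.
#' @export
simulate_dstat_graph <- function(n_snps,
                                 drift = c(root_internal = 0.05,
                                           internal_p12 = 0.05,
                                           p1 = 0.05, p2 = 0.05,
                                           p3 = 0.15, outgroup = 0.3),
                                 introgression_fraction = 0, seed = 1L,
                                 pos_bp = NULL) {
  stopifnot(introgression_fraction >= 0, introgression_fraction < 1)
  set.seed(seed)
  bn <- function(p, f) {
    if (f <= 0) return(p)
    q <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
    pmin(pmax(q, 1e-9), 1 - 1e-9)
  }
  p_root <- stats::runif(n_snps, 0.05, 0.95)
  pO <- bn(p_root, drift[["outgroup"]])
  p123 <- bn(p_root, drift[["root_internal"]])
  p3 <- bn(p123, drift[["p3"]])
  p12 <- bn(p123, drift[["internal_p12"]])
  p1 <- bn(p12, drift[["p1"]])
  p2 <- bn(p12, drift[["p2"]])
  mig <- stats::runif(n_snps) < introgression_fraction
  p2[mig] <- p3[mig]
  if (is.null(pos_bp)) pos_bp <- seq_len(n_snps) * 50000L  # ~50 kb array spacing
  list(p1 = p1, p2 = p2, p3 = p3, pO = pO, pos_bp = pos_bp,
       truth = list(seed = seed, drift = drift,
                    introgression_fraction = introgression_fraction,
                    migrated = mig))
}
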