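test_that("karyotype genome has the right chromosome and arm structure", {
  ka <- chinook_karyotype()
  cfg <- genome_config(ka)
  expect_equal(nrow(cfg$chromosomes), 34L)
  expect_equal(sum(cfg$chromosomes$type == "metacentric"), 16L)
  expect_equal(sum(cfg$chromosomes$type == "acrocentric"), 18L)
  # mappable arms: both arms of metacentrics plus q arms of acrocentrics
  mappable <- sum(cfg$chromosomes$type == "metacentric") * 2L +
    sum(cfg$chromosomes$type == "acrocentric")
  expect_equal(mappable, 50L)
  expect_equal(cfg$chromosomes$centromere, cfg$chromosomes$p_len)
})

test_that("genome building is deterministic by seed and validates inputs", {
  g1 <- one_chrom_genome(seed = 99)
  g2 <- one_chrom_genome(seed = 99)
  expect_identical(g1$loci$sequence, g2$loci$sequence)
  expect_identical(g1$alleles, g2$alleles)
  expect_true(all(nchar(g1$alleles$sequence) == 74L))

  # empty locus table is allowed
  ka <- data.frame(chrom = 1L, p_len = 10, q_len = 20)
  g0 <- build_genome(genome_config(ka, seed = 1))
  expect_equal(nrow(g0$loci), 0L)

  # locus beyond chromosome end rejected
  bad <- data.frame(locus_id = "X", chrom = 1L, pos = 99,
                    is_duplicated = FALSE, pair_id = NA, dup_class = NA,
                    paralog = NA)
  expect_error(build_genome(genome_config(ka, loci = bad)), "outside")

  # duplicated locus on an undeclared arm rejected
  ka2 <- data.frame(chrom = 1:2, p_len = c(50, 0), q_len = c(60, 80))
  hp <- data.frame(pair_id = "H1", chrom_a = 1L, arm_a = "q",
                   chrom_b = 2L, arm_b = "q", divergence = 2L)
  loci <- data.frame(locus_id = c("D_p1", "D_p2"), chrom = c(1L, 1L),
                     pos = c(20, 30), is_duplicated = TRUE,
                     pair_id = "H1_d01", dup_class = "BPP_ab_ac",
                     paralog = 1:2)
  expect_error(build_genome(genome_config(ka2, hp, loci)), "arms")
})

test_that("paralog alleles respect the declared divergence", {
  for (d in 1:3) {
    g <- dup_genome(n_dup_per_pair = 3, divergence = d, seed = 20 + d,
                    dup_classes = c(BPP_ab_cd = 1))
    al <- g$alleles[g$alleles$locus_id %in%
                      g$loci$locus_id[g$loci$is_duplicated], ]
    for (lid in unique(al$locus_id)) {
      seqs <- al$sequence[al$locus_id == lid]
      D <- hamming_matrix(seqs)
      expect_true(all(D[1, -1] == d))        # variants at distance d from a
      expect_true(all(D[upper.tri(D)] <= 2 * d))
    }
  }
})

test_that("complete interference places exactly one crossover per arm", {
  g <- one_chrom_genome()
  for (i in 1:50) {
    tet <- simulate_tetrad(g, 1L, interference = "complete")
    expect_equal(nrow(tet$crossovers), 2L)
    expect_setequal(tet$crossovers$arm, c("p", "q"))
  }
  # acrocentric: one arm, one crossover
  ka <- data.frame(chrom = 1L, p_len = 0, q_len = 80)
  loci <- data.frame(locus_id = "M1", chrom = 1L, pos = 40,
                     is_duplicated = FALSE, pair_id = NA, dup_class = NA,
                     paralog = NA)
  ga <- build_genome(genome_config(ka, loci = loci))
  tet <- simulate_tetrad(ga, 1L, interference = "complete")
  expect_equal(nrow(tet$crossovers), 1L)
  expect_error(simulate_tetrad(g, 1L, interference = "bogus"), "interference")
  expect_error(simulate_tetrad(g, 99L), "chromosome")
})

test_that("Poisson crossover counts match the arm length in Morgans", {
  g <- marker_genome(positions = c(10, 100), p_len = 50, q_len = 50)
  set.seed(31)
  counts <- replicate(10000, {
    tet <- simulate_tetrad(g, 1L, interference = "none")
    sum(tet$crossovers$arm == "q")
  })
  # 50 cM arm: Poisson mean 0.5 per tetrad; sample mean within 3 SE
  se <- sqrt(0.5 / 10000)
  expect_lt(abs(mean(counts) - 0.5), 3 * se)

  # vanishing arm: essentially no crossovers
  gtiny <- marker_genome(positions = 5e-5, p_len = 1e-4, q_len = 1e-4)
  set.seed(32)
  n_xo <- sum(replicate(200, nrow(simulate_tetrad(gtiny, 1L,
                                                  interference = "none")$crossovers)))
  expect_equal(n_xo, 0L)
})

test_that("haploid offspring carry exactly one maternal allele everywhere", {
  g <- one_chrom_genome(n_loci = 9)
  cr <- simulate_cross(g, cross_spec("haploid", 60), seed = 41)
  expect_true(all(cr$genotypes %in% c("a", "b")))
  expect_error(cross_spec("gynogenetic_diploid", 10, with_sire = TRUE),
               "sire")
  expect_error(cross_spec("haploid", 0), "n_offspring")
})

test_that("half-tetrad heterozygosity: 0 at centromere, 1 at terminus under complete interference", {
  g <- marker_genome(positions = c(50, 110))  # centromere at 50, q end 110
  cr <- simulate_cross(g, cross_spec("gynogenetic_diploid", 400,
                                     interference = "complete"), seed = 5)
  y <- het_fraction(cr$genotypes)
  expect_equal(unname(y["M01"]), 0)
  expect_equal(unname(y["M02"]), 1)
})

test_that("half-tetrad closed form y_k matches brute-force tetrad enumeration", {
  closed <- function(k) (2 / 3) * (1 - (-1 / 2)^k)
  for (k in 0:3) expect_equal(brute_force_yk(k), closed(k))
})

test_that("distal heterozygote fraction approaches 2/3 without interference", {
  # long arm so nearly every half-tetrad sees at least one crossover
  g <- marker_genome(positions = c(0.5, 449), p_len = 1, q_len = 448)
  cr <- simulate_cross(g, cross_spec("gynogenetic_diploid", 4000,
                                     interference = "none"), seed = 6)
  y <- unname(het_fraction(cr$genotypes)["M02"])
  se <- sqrt(2 / 3 * 1 / 3 / 4000)
  expect_lt(abs(y - 2 / 3), 3 * se + 0.002)  # + asymptote remainder
})

test_that("haploid recombination matches the Haldane prediction for the realized process", {
  # markers 40 cM apart on one arm; tetrad crossovers Poisson(arm Morgans),
  # each involving a given chromatid with probability 1/2, so the chromatid
  # switch count is Poisson(d) with d = 0.20 and rf = (1 - exp(-2d)) / 2
  g <- marker_genome(positions = c(60, 100), p_len = 50, q_len = 60)
  cr <- simulate_cross(g, cross_spec("haploid", 10000,
                                     interference = "none"), seed = 8)
  rec <- mean(cr$genotypes[, 1] != cr$genotypes[, 2])
  rf_expect <- (1 - exp(-2 * 0.20)) / 2
  se <- sqrt(rf_expect * (1 - rf_expect) / 10000)
  expect_lt(abs(rec - rf_expect), 3 * se)
})

test_that("gamma-interference crossovers interpolate between Poisson and regular", {
  g <- marker_genome(positions = 50, p_len = 1, q_len = 199)
  set.seed(77)
  counts <- replicate(2000, nrow(simulate_tetrad(g, 1L, interference = "gamma",
                                                 nu = 8)$crossovers))
  expect_lt(abs(mean(counts) - 2), 0.15)      # rate preserved (2 Morgans)
  expect_lt(var(counts), mean(counts))        # underdispersed vs Poisson
})

test_that("read simulation respects depth, error and allele balance", {
  g <- marker_genome(positions = c(10, 100))
  G <- matrix(c("a", "a/b"), nrow = 1,
              dimnames = list("I1", c("M01", "M02")))
  pp <- simulate_reads(g, G, mean_depth = 20, depth_dispersion = 1e6,
                       error_rate = 0, seed = 3)
  hom <- pp[pp$locus_id == "M01", ]
  expect_equal(nrow(hom), 1L)   # error-free homozygote: single sequence
  expect_equal(hom$sequence,
               g$alleles$sequence[g$alleles$locus_id == "M01" &
                                    g$alleles$allele == "a"])

  # heterozygote allele balance: binomial expectation over many individuals
  G2 <- matrix(rep("a/b", 800), ncol = 1,
               dimnames = list(sprintf("I%03d", 1:800), "M02"))
  pp2 <- simulate_reads(g, G2, mean_depth = 30, depth_dispersion = 10,
                        error_rate = 0, seed = 4)
  seq_a <- g$alleles$sequence[g$alleles$locus_id == "M02" &
                                g$alleles$allele == "a"]
  frac_a <- sum(pp2$depth[pp2$sequence == seq_a]) / sum(pp2$depth)
  se <- sqrt(0.25 / sum(pp2$depth))
  expect_lt(abs(frac_a - 0.5), 3 * se)

  # error reads appear as novel third-allele sequences
  pp3 <- simulate_reads(g, G2[1:50, , drop = FALSE], mean_depth = 30,
                        depth_dispersion = 10, error_rate = 0.05, seed = 5)
  known <- g$alleles$sequence[g$alleles$locus_id == "M02"]
  expect_gt(sum(pp3$depth[!pp3$sequence %in% known]), 0)
  expect_error(simulate_reads(g, G2, mean_depth = 0), "mean_depth")
  expect_error(simulate_reads(g, G2, mean_depth = 5, error_rate = 1),
               "error_rate")
})
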