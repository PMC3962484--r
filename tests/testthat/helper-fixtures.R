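# Shared in-code fixtures: small genomes and crosses built fresh per test.

# one metacentric chromosome with evenly spaced markers
one_chrom_genome <- function(p_len = 50, q_len = 60, n_loci = 11, seed = 7) {
  ka <- data.frame(chrom = 1L, p_len = p_len, q_len = q_len)
  loci <- data.frame(locus_id = sprintf("M%02d", seq_len(n_loci)),
                     chrom = 1L,
                     pos = seq(0, p_len + q_len, length.out = n_loci),
                     is_duplicated = FALSE, pair_id = NA_character_,
                     dup_class = NA_character_, paralog = NA_integer_)
  build_genome(genome_config(ka, loci = loci, seed = seed))
}

# genome with markers at chosen positions only
marker_genome <- function(positions, p_len = 50, q_len = 60, seed = 7) {
  ka <- data.frame(chrom = 1L, p_len = p_len, q_len = q_len)
  loci <- data.frame(locus_id = sprintf("M%02d", seq_along(positions)),
                     chrom = 1L, pos = positions,
                     is_duplicated = FALSE, pair_id = NA_character_,
                     dup_class = NA_character_, paralog = NA_integer_)
  build_genome(genome_config(ka, loci = loci, seed = seed))
}

# two-chromosome genome carrying duplicated paralog pairs on the q arms
dup_genome <- function(n_unique_per_chrom = 10, n_dup_per_pair = 4,
                       divergence = 2L, seed = 11,
                       dup_classes = c(OPP_aa_ab = 0.35, OPP_aa_bc = 0.15,
                                       BPP_ab_ac = 0.25, BPP_ab_cd = 0.15,
                                       aa_bb = 0.05, ab_ab = 0.05)) {
  ka <- data.frame(chrom = 1:2, p_len = c(50, 0), q_len = c(60, 80))
  hp <- data.frame(pair_id = "H1", chrom_a = 1L, arm_a = "q",
                   chrom_b = 2L, arm_b = "q", divergence = divergence)
  cfg0 <- genome_config(ka, hp)
  loci <- place_loci(cfg0$chromosomes, hp, n_per_chrom = n_unique_per_chrom,
                     n_dup_per_pair = n_dup_per_pair,
                     dup_classes = dup_classes, seed = seed)
  build_genome(genome_config(ka, hp, loci, seed = seed + 1L))
}

# heterozygote fraction per locus of a gynogenetic-diploid genotype matrix
het_fraction <- function(G) {
  apply(G, 2, function(col) {
    ok <- !is.na(col)
    mean(substr(col[ok], 1, 1) != substr(col[ok], 3, 3))
  })
}

# brute-force half-tetrad oracle: enumerate all chromatid choices for k
# crossovers between locus and centromere, return heterozygote fraction
brute_force_yk <- function(k) {
  if (k == 0) return(0)
  combos <- expand.grid(rep(list(1:4), k))
  het <- 0; tot <- 0
  for (r in seq_len(nrow(combos))) {
    H <- c(1, 1, 2, 2)
    for (cc in seq_len(k)) {
      ij <- combos[r, cc]
      i <- c(1, 1, 2, 2)[ij]; j <- c(3, 4, 3, 4)[ij]
      tmp <- H[i]; H[i] <- H[j]; H[j] <- tmp
    }
    for (pole in c(0, 2)) {
      tot <- tot + 1
      het <- het + (H[pole + 1] != H[pole + 2])
    }
  }
  het / tot
}

# exhaustive permutation oracle for marker-order objective
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
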