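test_that("hamming_matrix agrees with the Biostrings distance oracle", {
  set.seed(101)
  seqs <- random_seq(40)
  D <- hamming_matrix(seqs)
  oracle <- as.matrix(Biostrings::stringDist(Biostrings::DNAStringSet(seqs),
                                             method = "hamming"))
  dimnames(oracle) <- NULL
  expect_equal(unname(D), unname(oracle), ignore_attr = TRUE)
  expect_error(hamming_matrix(c("ACGT", "ACG")), "length")
})

test_that("consensus is depth-weighted majority with lexicographic ties", {
  expect_equal(consensus_seq(c("AAAA", "AAAT", "AAAT")), "AAAT")
  expect_equal(consensus_seq(c("AAAA", "AAAT"), weights = c(5, 1)), "AAAA")
  # tie at last position: A < T wins
  expect_equal(consensus_seq(c("AAAA", "AAAT")), "AAAA")
  expect_equal(consensus_seq(c("GGGT", "GGGA")), "GGGA")
})

test_that("clustering separates loci beyond the mismatch radius and merges within it", {
  set.seed(7)
  base <- random_seq(1)
  near <- mutate_seq(base, 2)
  far <- mutate_seq(base, 4)
  pp <- data.frame(individual_id = "I1",
                   sequence = c(base, near), depth = c(10L, 8L))
  cl <- cluster_reads(pp)
  expect_equal(nrow(cl$clusters), 1L)

  pp2 <- data.frame(individual_id = "I1",
                    sequence = c(base, far), depth = c(10L, 8L))
  cl2 <- cluster_reads(pp2)
  expect_equal(nrow(cl2$clusters), 2L)
  expect_error(cluster_reads(data.frame(individual_id = "I1",
                                        sequence = "ACGT", depth = 1L)),
               "74")
})

test_that("error-free simulated loci are recovered one cluster per locus", {
  g <- dup_genome(n_unique_per_chrom = 45, n_dup_per_pair = 5, seed = 51)
  panel <- simulate_panel(g, 20, seed = 52)
  pp <- simulate_reads(g, panel, mean_depth = 25, error_rate = 0, seed = 53)
  cl <- cluster_reads(pp)
  # every duplicated pair collapses to one cluster: 90 unique + 5 composite
  expect_equal(nrow(cl$clusters), 95L)
  expect_equal(length(cl$ambiguous), 0L)
  # each true unique locus consensus is represented
  uniq <- g$loci[!g$loci$is_duplicated, ]
  D <- hamming_matrix(uniq$sequence, cl$clusters$consensus)
  expect_true(all(apply(D, 1, min) <= 1))
})

test_that("coverage filter applies the strict depth-and-fraction rule", {
  depth <- matrix(0L, 2, 100,
                  dimnames = list(c("C1", "C2"), sprintf("I%03d", 1:100)))
  depth[1, 1:90] <- 6L   # >5X in 90% of individuals
  depth[2, 1:84] <- 6L   # only 84%
  clustering <- list(clusters = data.frame(cluster_id = c("C1", "C2"),
                                           consensus = random_seq(2),
                                           n_sequences = 1L,
                                           total_depth = rowSums(depth)),
                     depth = depth)
  db <- coverage_filter(clustering, 100)
  expect_equal(db$status, c("candidate", "excluded_coverage"))
  expect_error(coverage_filter(clustering, 0), "positive")

  # all-zero depth: nothing survives
  clustering$depth[] <- 0L
  expect_true(all(coverage_filter(clustering, 100)$status ==
                    "excluded_coverage"))
})

test_that("self-alignment screen excludes repeat-like loci symmetrically", {
  set.seed(61)
  base <- random_seq(1)
  db <- data.frame(locus_id = c("A", "B", "C"),
                   sequence = c(base, mutate_seq(base, 3),
                                random_seq(1)),
                   status = "candidate")
  out <- self_align_screen(db)
  expect_equal(out$status, c("excluded_multimap", "excluded_multimap",
                             "candidate"))
  # single-locus database: self-match only, retained
  solo <- self_align_screen(data.frame(locus_id = "A", sequence = base,
                                       status = "candidate"))
  expect_equal(solo$status, "candidate")
})

test_that("low-complexity screen masks repeats but not random sequence", {
  dinuc <- paste(rep(c("A", "C"), 37), collapse = "")
  mono <- paste(rep("G", 74), collapse = "")
  set.seed(71)
  rand <- random_seq(5000)
  db <- data.frame(locus_id = c("d", "m", sprintf("r%04d", 1:5000)),
                   sequence = c(dinuc, mono, rand), status = "candidate")
  out <- low_complexity_screen(db)
  expect_equal(out$status[1:2], rep("excluded_lowcomplexity", 2))
  # false-masking rate on uniform-random 74-mers below 1%
  expect_lt(mean(out$status[-(1:2)] == "excluded_lowcomplexity"), 0.01)
})

test_that("duplicate identification needs more than one heterozygous haploid", {
  db <- data.frame(locus_id = c("L1", "L2"), sequence = random_seq(2),
                   status = "candidate")
  fam <- matrix(c("a/b", "a/b", "a/a", "a/a",
                  "a/b", "a/a", "a/a", "a/a"),
                nrow = 4, dimnames = list(sprintf("I%d", 1:4), c("L1", "L2")))
  attr(fam, "cross_type") <- "haploid"
  out <- identify_duplicates(db, list(F1 = fam))
  expect_equal(out$status, c("duplicated", "unique"))

  bad <- fam
  attr(bad, "cross_type") <- "diploid"
  expect_error(identify_duplicates(db, list(F1 = bad)), "haploid")
})

test_that("zero-error duplicate detection is exact against simulation truth", {
  g <- dup_genome(n_unique_per_chrom = 20, n_dup_per_pair = 8, seed = 81,
                  dup_classes = c(OPP_aa_ab = 0.4, BPP_ab_ac = 0.3,
                                  BPP_ab_cd = 0.3))
  panel <- simulate_panel(g, 24, seed = 82)
  panel_pp <- simulate_reads(g, panel, mean_depth = 25, error_rate = 0,
                             seed = 83)
  hap <- simulate_cross(g, cross_spec("haploid", 30, family_id = "A"),
                        seed = 84)
  hap_pp <- simulate_reads(g, hap$genotypes, mean_depth = 25, error_rate = 0,
                           seed = 85)
  res <- build_refdb(panel_pp, list(A = hap_pp))
  db <- res$db
  # map database loci back to truth by sequence
  truth_dup <- g$loci[g$loci$is_duplicated, ]
  truth_uni <- g$loci[!g$loci$is_duplicated, ]
  D_dup <- hamming_matrix(db$sequence, truth_dup$sequence)
  is_true_dup <- apply(D_dup, 1, min) <= 3
  # sensitivity: every collapsed paralog cluster flagged duplicated
  expect_true(all(db$status[is_true_dup] == "duplicated"))
  expect_equal(sum(db$status == "duplicated"), 8L)
  # specificity 1.0: no unique locus flagged
  expect_true(all(db$status[!is_true_dup] %in%
                    c("unique", "excluded_multimap",
                      "excluded_lowcomplexity", "excluded_coverage")))
  expect_false(any(db$status[!is_true_dup] == "duplicated"))
})

test_that("screening statuses partition the input and survive a FASTA round trip", {
  g <- dup_genome(n_unique_per_chrom = 10, n_dup_per_pair = 3, seed = 91)
  panel <- simulate_panel(g, 16, seed = 92)
  pp <- simulate_reads(g, panel, mean_depth = 20, error_rate = 0.01,
                       seed = 93)
  res <- build_refdb(pp, list())
  statuses <- c("unique", "duplicated", "candidate", "excluded_coverage",
                "excluded_multimap", "excluded_lowcomplexity")
  expect_true(all(res$db$status %in% statuses))
  expect_equal(nrow(res$db), nrow(res$clustering$clusters))
  retained <- res$db[!startsWith(res$db$status, "excluded"), ]
  expect_false(any(duplicated(retained$sequence)))
  expect_true(all(nchar(retained$sequence) == 74L))

  fa <- tempfile(fileext = ".fasta")
  write_refdb_fasta(res$db, fa)
  back <- read_refdb_fasta(fa)
  expect_equal(back$locus_id, res$db$locus_id)
  expect_equal(back$sequence, res$db$sequence)
  expect_equal(back$status, res$db$status)
})
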