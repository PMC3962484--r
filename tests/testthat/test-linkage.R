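test_that("two-point statistics match the closed form", {
  x <- rep(c("a", "b"), 23)
  r <- two_point(x, x)
  expect_equal(unname(r["rf"]), 0)
  expect_equal(unname(r["lod"]), 46 * log10(2), tolerance = 1e-10)

  # 23 recombinants of 46: independence
  y <- c(x[1:23], ifelse(x[24:46] == "a", "b", "a"))
  r2 <- two_point(x, y)
  expect_equal(unname(r2["rf"]), 0.5)
  expect_equal(unname(r2["lod"]), 0, tolerance = 1e-10)

  # phase swap: R -> n - R, rf' = 1 - rf before clamping
  set.seed(301)
  a <- sample(c("a", "b"), 40, replace = TRUE)
  b <- sample(c("a", "b"), 40, replace = TRUE)
  swapped <- ifelse(b == "a", "b", "a")
  r3 <- two_point(a, b)
  r4 <- two_point(a, swapped)
  expect_equal(unname(r4["R"]), 40 - unname(r3["R"]))
  expect_error(two_point("a", "b"), "jointly scored")
})

test_that("grouping separates independent chromosomes and escalation isolates markers", {
  ka <- data.frame(chrom = 1:2, p_len = c(0, 0), q_len = c(60, 60))
  loci <- data.frame(locus_id = sprintf("M%d_%d", rep(1:2, each = 6), 1:6),
                     chrom = rep(1:2, each = 6),
                     pos = rep(seq(5, 55, by = 10), 2),
                     is_duplicated = FALSE, pair_id = NA, dup_class = NA,
                     paralog = NA)
  g <- build_genome(genome_config(ka, loci = loci, seed = 311))
  cr <- simulate_cross(g, cross_spec("haploid", 50), seed = 312)
  X <- binarize_haploid(matrix(paste0(cr$genotypes, "/", cr$genotypes),
                               nrow = nrow(cr$genotypes),
                               dimnames = dimnames(cr$genotypes)))
  tp <- two_point_table(X)
  grp <- form_groups(tp, linkage_params(target_groups = 2L))
  expect_equal(grp$n_groups, 2L)
  split_by_truth <- split(names(grp$groups), grp$groups)
  expect_setequal(vapply(split_by_truth, function(mk)
    length(unique(substr(mk, 2, 2))), integer(1)), c(1L, 1L))

  # absurdly high starting LOD: every marker its own group
  grp_inf <- form_groups(tp, linkage_params(lod_start = 1e6,
                                            target_groups = 2L))
  expect_equal(grp_inf$n_groups, ncol(X))

  expect_error(form_groups(tp, linkage_params(target_groups = 50L)),
               "fewer markers")

  # partition invariant under marker input order
  perm <- sample(ncol(X))
  grp_perm <- form_groups(two_point_table(X[, perm]),
                          linkage_params(target_groups = 2L))
  for (pair in list(c("M1_1", "M1_3"), c("M2_2", "M2_5"))) {
    expect_equal(grp_perm$groups[pair[1]] == grp_perm$groups[pair[2]],
                 grp$groups[pair[1]] == grp$groups[pair[2]])
  }
})

test_that("three markers order by recombinant counts and bins collapse", {
  # construct haploid phases with r(AB)=2, r(BC)=3, r(AC)=5 of 46
  A <- rep(0L, 46)
  B <- A; B[1:2] <- 1L          # 2 recombinants A-B
  C <- B; C[10:12] <- 1L        # 3 recombinants B-C, 5 A-C
  X <- cbind(A = A, B = B, C = C)
  rownames(X) <- sprintf("I%02d", 1:46)
  ord <- order_markers(c("A", "B", "C"), X,
                       linkage_params(map_function = "morgan"))
  expect_equal(ord$marker, c("A", "B", "C"))
  expect_equal(ord$position, c(0, 2 / 46, 5 / 46) * 100, tolerance = 1e-10)

  # fully co-segregating markers form a single zero-length bin
  Xb <- cbind(A = A, B = A, C = A)
  rownames(Xb) <- rownames(X)
  ordb <- order_markers(c("A", "B", "C"), Xb, linkage_params())
  expect_equal(unique(ordb$position), 0)
  expect_equal(unique(ordb$bin), "A")

  # single marker: position 0
  expect_equal(order_markers("A", X)$position, 0)
})

test_that("returned order is never worse than the brute-force optimum on small groups", {
  set.seed(321)
  for (rep in 1:5) {
    n_mark <- sample(5:8, 1)
    g <- marker_genome(positions = sort(runif(n_mark, 51, 110)))
    cr <- simulate_cross(g, cross_spec("haploid", 40), seed = 321 + rep)
    X <- binarize_haploid(matrix(paste0(cr$genotypes, "/", cr$genotypes),
                                 nrow = nrow(cr$genotypes),
                                 dimnames = dimnames(cr$genotypes)))
    keep <- colnames(X)[colSums(!is.na(X)) > 0]
    tp <- two_point_table(X[, keep, drop = FALSE])
    ord <- order_markers(keep, X, linkage_params())
    reps <- unique(ord$bin)
    if (length(reps) < 3) next
    ri <- match(reps, keep)
    R <- tp$R[ri, ri]
    obj <- function(o) sum(R[cbind(o[-length(o)], o[-1])])
    returned <- obj(match(unique(ord$bin), reps))
    perms <- all_permutations(length(reps))
    best <- min(apply(perms, 1, obj))
    expect_equal(returned, best)
  }
})

test_that("dense markers under complete interference recover 50 cM per arm", {
  pos <- c(seq(0.5, 49.5, length.out = 20), seq(50.5, 109.5, length.out = 20))
  g <- marker_genome(positions = pos, p_len = 50, q_len = 60)
  cr <- simulate_cross(g, cross_spec("haploid", 1000), seed = 331)
  X <- binarize_haploid(matrix(paste0(cr$genotypes, "/", cr$genotypes),
                               nrow = nrow(cr$genotypes),
                               dimnames = dimnames(cr$genotypes)))
  ord <- order_markers(colnames(X), X, linkage_params(map_function = "morgan"))
  # per-arm genetic length: obligate single crossover = 50 cM per arm;
  # markers cover 98% (p) and 98% (q) of each arm
  p_span <- diff(range(ord$position[ord$marker %in% sprintf("M%02d", 1:20)]))
  q_span <- diff(range(ord$position[ord$marker %in% sprintf("M%02d", 21:40)]))
  expect_lt(abs(p_span - 49), 5)
  expect_lt(abs(q_span - 49), 5)
  total <- max(ord$position)
  expect_lt(abs(total - 98) / 98, 0.10)
  # recovered order matches the simulated order (up to orientation)
  got <- unique(ord$marker)
  expect_true(identical(got, sprintf("M%02d", 1:40)) ||
                identical(got, sprintf("M%02d", 40:1)))
})

test_that("consensus merging is idempotent, unioning and conflict-aware", {
  m1 <- data.frame(group = "LG1", marker = c("A", "B", "C"),
                   position = c(0, 10, 20))
  # identical maps: consensus identical (any number of copies)
  cons <- merge_maps(list(F1 = m1, F2 = m1, F3 = m1))
  expect_equal(cons$map$marker, c("A", "B", "C"))
  expect_equal(cons$map$position, c(0, 10, 20))
  expect_equal(nrow(cons$conflicts), 0L)

  # overlapping marker sets union in a consistent order
  m2 <- data.frame(group = "LG1", marker = c("B", "C", "D"),
                   position = c(0, 10, 20))
  cons2 <- merge_maps(list(F1 = m1, F2 = m2))
  expect_equal(cons2$map$marker, c("A", "B", "C", "D"))
  expect_true(all(diff(cons2$map$position) >= 0))

  # conflicting order: one of the pair dropped and reported
  m3 <- data.frame(group = "LG1", marker = c("A", "C", "B", "D"),
                   position = c(0, 8, 16, 24))
  cons3 <- merge_maps(list(F1 = rbind(m1, data.frame(group = "LG1",
                                                     marker = "D",
                                                     position = 30)),
                           F2 = m3))
  expect_equal(nrow(cons3$conflicts), 1L)
  expect_true(cons3$conflicts$marker %in% c("B", "C"))
  expect_false(cons3$conflicts$marker %in% cons3$map$marker)

  # a flipped family map merges as if unflipped
  m1_flipped <- data.frame(group = "LG1", marker = c("C", "B", "A"),
                           position = c(0, 10, 20))
  cons4 <- merge_maps(list(F1 = m1, F2 = m1_flipped))
  expect_equal(cons4$map$marker, c("A", "B", "C"))
  expect_error(merge_maps(list(F1 = m1)), "at least 2")
})

test_that("anchoring labels groups by majority and orients p arm first", {
  map <- data.frame(group = rep("G1", 4), marker = c("A", "B", "C", "D"),
                    position = c(0, 10, 20, 30))
  anchors <- data.frame(marker = c("A", "B", "D"),
                        chrom = c("chr7", "chr7", "chr9"),
                        arm = c("q", "q", "p"))
  res <- anchor_groups(map, anchors)
  expect_true(all(res$map$chrom == "chr7"))
  expect_equal(res$conflicts$chrom, "chr9")
  # p anchor (D) was at the end: group flipped so it comes first
  expect_equal(res$map$marker[res$map$position == 0], "D")

  # group with no anchors stays unlabelled
  map2 <- data.frame(group = "G2", marker = "Z", position = 0)
  res2 <- anchor_groups(map2, anchors)
  expect_true(is.na(res2$map$chrom))
})

test_that("map functions agree at small distances and diverge as expected", {
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0.1, "morgan"), 10)
  expect_lt(map_distance(0.1, "kosambi"), map_distance(0.1, "haldane"))
  expect_equal(map_distance(0.01, "kosambi"), 1, tolerance = 0.01)
  expect_error(map_distance(0.1, "carter"), "map function")
})
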