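#' Screening parameters for reference-database construction and genotyping
#'
#' Defaults follow the published RAD screening rules: a locus enters the
#' temporary database when sequenced at depth greater than 5 reads in more
#' than 85\% of individuals; loci are distinct when they differ at more than
#' 3 of 74 nucleotides; genotypes need at least 10 reads; a locus is
#' duplicated when 2 or more haploid individuals are heterozygous in one
#' family (one heterozygous haploid can be a sequencing error, the same
#' error twice is deemed unlikely).
#'
#' @param min_depth_per_locus per-individual depth that counts as "sequenced"
#'   (strictly greater than; default 5).
#' @param min_individual_fraction fraction of individuals that must pass the
#'   depth rule (strictly greater than; default 0.85).
#' @param max_mismatch maximum nucleotide mismatches for two sequences to be
#'   treated as one locus (default 3).
#' @param min_reads_for_genotype minimum total depth for a genotype call
#'   (default 10).
#' @param min_het_haploids_for_duplicate heterozygous haploids within one
#'   family needed to flag a locus duplicated (default 2).
#' @param low_complexity_threshold DUST-style triplet score above which a
#'   locus is excluded as low complexity.  The default 1.0 was calibrated on
#'   uniform-random 74-mers so that fewer than 1\% are masked, while
#'   dinucleotide and mononucleotide repeats score an order of magnitude
#'   higher.
#' @return an object of class \code{screening_params}.
#' @export
screening_params <- function(min_depth_per_locus = 5L,
                             min_individual_fraction = 0.85,
                             max_mismatch = 3L,
                             min_reads_for_genotype = 10L,
                             min_het_haploids_for_duplicate = 2L,
                             low_complexity_threshold = 1.0) {
  p <- list(min_depth_per_locus = min_depth_per_locus,
            min_individual_fraction = min_individual_fraction,
            max_mismatch = as.integer(max_mismatch),
            min_reads_for_genotype = min_reads_for_genotype,
            min_het_haploids_for_duplicate = min_het_haploids_for_duplicate,
            low_complexity_threshold = low_complexity_threshold)
  if (any(unlist(p) <= 0)) stopf("all screening thresholds must be positive")
  if (p$max_mismatch > 74L) stopf("max_mismatch cannot exceed locus length")
  structure(p, class = "screening_params")
}

#' Cluster pileup sequences into candidate loci
#'
#' De-novo locus discovery: unique read sequences are pooled across
#' individuals and clustered so that sequences within \code{max_mismatch} of
#' one cluster consensus (and farther from every other) join that cluster.
#' Seeding is greedy by total read depth; consensi are depth-weighted
#' majority sequences recomputed once, followed by a final assignment pass.
#' A sequence within \code{max_mismatch} of two or more consensi is flagged
#' ambiguous and left unassigned.
#'
#' @param pileups pileup data.frame (\code{individual_id}, \code{sequence},
#'   \code{depth}); any \code{locus_id} column is ignored.
#' @param params a [screening_params()].
#' @return list with \code{clusters} (cluster_id, consensus, n_sequences,
#'   total_depth), \code{depth} (matrix cluster x individual of summed
#'   depth), and \code{ambiguous} (character vector of unassigned sequences).
#' @export
cluster_reads <- function(pileups, params = screening_params()) {
  if (any(nchar(pileups$sequence) != 74L))
    stopf("pileup sequences must be 74 nt")
  agg <- aggregate(depth ~ sequence, pileups, sum)
  agg <- agg[order(-agg$depth, agg$sequence), ]
  seqs <- agg$sequence
  mm <- params$max_mismatch
  # single-linkage components over sequences at <= max_mismatch: alleles of
  # one locus (including collapsed paralog alleles) chain together, while
  # distinct loci stay apart; adjacency is computed in row chunks to bound
  # memory on large sequence sets
  edges <- list()
  chunk <- 1000L
  for (s in seq(1L, length(seqs), by = chunk)) {
    rows <- s:min(s + chunk - 1L, length(seqs))
    Dch <- hamming_matrix(seqs[rows], seqs)
    hit <- which(Dch <= mm, arr.ind = TRUE)
    hit[, 1] <- rows[hit[, 1]]
    edges[[length(edges) + 1L]] <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(seqs) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # depth-weighted consensus per component, then a final assignment pass
  consensi <- vapply(seq_len(max(memb)), function(m) {
    consensus_seq(seqs[memb == m], agg$depth[memb == m])
  }, character(1))
  Dc <- hamming_matrix(seqs, consensi)
  n_near <- rowSums(Dc <= mm)
  assign <- ifelse(n_near == 1L, apply(Dc, 1L, which.min), NA_integer_)
  ambiguous <- seqs[n_near > 1L]
  keep <- !is.na(assign)
  cluster_ids <- sprintf("C%05d", seq_along(consensi))
  per_ind <- pileups[pileups$sequence %in% seqs[keep], ]
  per_ind$cluster <- cluster_ids[assign[match(per_ind$sequence, seqs)]]
  depth_tab <- tapply(per_ind$depth,
                      list(factor(per_ind$cluster, levels = cluster_ids),
                           per_ind$individual_id), sum, default = 0L)
  clusters <- data.frame(
    cluster_id = cluster_ids, consensus = consensi,
    n_sequences = as.integer(table(factor(assign, levels = seq_along(consensi)))),
    total_depth = as.numeric(tapply(agg$depth[keep],
                                    factor(assign[keep], levels = seq_along(consensi)),
                                    sum, default = 0)))
  empty <- clusters$n_sequences == 0L
  list(clusters = clusters[!empty, , drop = FALSE],
       depth = depth_tab[!empty, , drop = FALSE],
       ambiguous = ambiguous)
}

#' Coverage-filter candidate loci into a temporary database
#'
#' Retains clusters sequenced at depth greater than
#' \code{min_depth_per_locus} in more than \code{min_individual_fraction}
#' of the panel individuals; all others are \code{excluded_coverage}.
#'
#' @param clustering result of [cluster_reads()].
#' @param n_individuals panel size the fraction refers to (> 0).
#' @param params a [screening_params()].
#' @return a refdb data.frame: \code{locus_id}, \code{sequence},
#'   \code{status} (\code{candidate} for retained loci at this stage),
#'   \code{n_pass} individuals passing the depth rule.
#' @export
coverage_filter <- function(clustering, n_individuals,
                            params = screening_params()) {
  if (n_individuals <= 0L) stopf("n_individuals must be positive")
  n_pass <- rowSums(clustering$depth > params$min_depth_per_locus)
  ok <- n_pass > params$min_individual_fraction * n_individuals
  data.frame(locus_id = clustering$clusters$cluster_id,
             sequence = clustering$clusters$consensus,
             status = ifelse(ok, "candidate", "excluded_coverage"),
             n_pass = as.integer(n_pass))
}

#' Exclude repeat-like loci that align to several database loci
#'
#' Every retained locus is compared against the whole database; a locus
#' within \code{max_mismatch} of any other database locus (besides its exact
#' self) is likely a repeat sequence, and the entire matching set is
#' excluded as \code{excluded_multimap}.  The relation is symmetric by
#' construction.
#'
#' @param db refdb data.frame from [coverage_filter()].
#' @param params a [screening_params()].
#' @return the database with \code{status} updated.
#' @export
self_align_screen <- function(db, params = screening_params()) {
  live <- which(db$status == "candidate")
  if (!length(live)) return(db)
  D <- hamming_matrix(db$sequence[live])
  n_hits <- rowSums(D <= params$max_mismatch)  # includes self
  db$status[live[n_hits > 1L]] <- "excluded_multimap"
  db
}

#' DUST-style low-complexity score of a sequence
#'
#' Overlapping-triplet collision statistic: with \eqn{c_t} the count of
#' triplet \eqn{t} among the \eqn{k} overlapping 3-mers of the sequence, the
#' score is \eqn{\sum_t c_t (c_t - 1) / 2 / (k - 1)}.  Uniform-random
#' 74-mers score about 0.56 on average; mono- and dinucleotide repeats score
#' 36 and 18.
#'
#' @param seqs character vector of sequences.
#' @return numeric vector of scores.
#' @export
dust_score <- function(seqs) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    tri <- paste0(ch[1:(n - 2)], ch[2:(n - 1)], ch[3:n])
    c_t <- table(tri)
    sum(c_t * (c_t - 1) / 2) / (length(tri) - 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Exclude low-complexity loci
#'
#' Replaces the self-BLAST-with-low-complexity-filter screen: loci whose
#' [dust_score()] exceeds \code{low_complexity_threshold} are marked
#' \code{excluded_lowcomplexity}.
#'
#' @inheritParams self_align_screen
#' @return the database with \code{status} updated.
#' @export
low_complexity_screen <- function(db, params = screening_params()) {
  live <- which(db$status == "candidate")
  if (!length(live)) return(db)
  sc <- dust_score(db$sequence[live])
  db$status[live[sc > params$low_complexity_threshold]] <- "excluded_lowcomplexity"
  db
}

#' Identify duplicated loci from heterozygous haploids
#'
#' A haploid offspring carries a single maternal chromatid, so it is
#' hemizygous (scored homozygous) at every non-duplicated locus; an apparent
#' heterozygote means reads from two collapsed paralogs.  One heterozygous
#' haploid could be a sequencing error and is insufficient evidence; a locus
#' is flagged \code{duplicated} when at least
#' \code{min_het_haploids_for_duplicate} haploids of a single family are
#' heterozygous.  Evidence is deliberately not weighted by family size.
#'
#' @param db refdb data.frame (post screening).
#' @param haploid_calls named list of per-family genotype call matrices
#'   (individuals x database loci, entries \code{"x/y"} or NA) derived from
#'   haploid offspring; each matrix may carry a \code{cross_type} attribute,
#'   which must be \code{"haploid"} if present.
#' @param params a [screening_params()].
#' @return the database with retained loci set to \code{duplicated} or
#'   \code{unique}.
#' @export
identify_duplicates <- function(db, haploid_calls,
                                params = screening_params()) {
  for (fam in names(haploid_calls)) {
    ct <- attr(haploid_calls[[fam]], "cross_type")
    if (!is.null(ct) && ct != "haploid")
      stopf("family %s: duplicate identification requires haploid calls, got %s",
            fam, ct)
  }
  live <- which(db$status == "candidate")
  dup <- rep(FALSE, length(live))
  for (fam in haploid_calls) {
    present <- intersect(colnames(fam), db$locus_id[live])
    if (!length(present)) next
    het_n <- colSums(matrix(is_het_geno(fam[, present, drop = FALSE]),
                            nrow = nrow(fam)), na.rm = TRUE)
    dup[match(present, db$locus_id[live])] <-
      dup[match(present, db$locus_id[live])] |
      (het_n >= params$min_het_haploids_for_duplicate)
  }
  db$status[live] <- ifelse(dup, "duplicated", "unique")
  db
}

#' Build the full reference database from pileups
#'
#' Runs the fixed screening order: clustering, coverage filter,
#' self-alignment screen, low-complexity screen, then duplicate
#' identification from haploid families (reads aligned back to the screened
#' database and genotyped under the depth rules).
#'
#' @param panel_pileups pileups of the locus-discovery panel.
#' @param haploid_pileups named list of pileup data.frames, one per haploid
#'   family.
#' @param n_individuals panel size (defaults to the individuals present in
#'   \code{panel_pileups}).
#' @param params a [screening_params()].
#' @return list with \code{db} (refdb data.frame), \code{haploid_calls}
#'   (per-family call matrices) and \code{clustering}.
#' @export
build_refdb <- function(panel_pileups, haploid_pileups = list(),
                        n_individuals = NULL,
                        params = screening_params()) {
  clustering <- cluster_reads(panel_pileups, params)
  if (is.null(n_individuals))
    n_individuals <- length(unique(panel_pileups$individual_id))
  db <- coverage_filter(clustering, n_individuals, params)
  db <- self_align_screen(db, params)
  db <- low_complexity_screen(db, params)
  calls <- lapply(haploid_pileups, function(pp) {
    assigned <- align_to_db(pp, db, params)
    m <- call_genotype_matrix(assigned, params)
    attr(m, "cross_type") <- "haploid"
    m
  })
  db <- identify_duplicates(db, calls, params)
  list(db = db, haploid_calls = calls, clustering = clustering)
}
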