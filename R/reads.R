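#' Simulate read pileups from true genotypes
#'
#' Per individual and locus, total read depth is drawn negative-binomial
#' (mean \code{mean_depth}, dispersion \code{size = depth_dispersion}; large
#' dispersion approaches Poisson) and reads are split over the individual's
#' true alleles by multinomial sampling.  Each read is independently turned
#' into a sequencing-error read with probability \code{error_rate}.  By
#' default an error read carries a novel sequence (the source allele mutated
#' at one random site), so error-driven false heterozygotes in haploids
#' remain detectable as third alleles; \code{error_mode = "parental"} instead
#' flips the read to the other parental allele, which stress-tests the
#' more-than-one-heterozygous-haploid duplicate rule.
#'
#' @param genome a [build_genome()] result (supplies allele sequences).
#' @param genotypes character matrix individuals x loci from
#'   [simulate_cross()] or [simulate_panel()] (\code{"a"} or \code{"a/b"}).
#' @param mean_depth mean total depth per locus per individual (> 0).
#' @param depth_dispersion negative-binomial size parameter.
#' @param error_rate per-read error probability in [0, 1).
#' @param error_mode \code{"novel"} or \code{"parental"}.
#' @param seed RNG seed.
#' @return data.frame pileup: \code{individual_id}, \code{locus_id} (truth
#'   provenance; the database builder ignores it), \code{sequence},
#'   \code{depth}.
#' @export
simulate_reads <- function(genome, genotypes, mean_depth = 30,
                           depth_dispersion = 10, error_rate = 0.005,
                           error_mode = c("novel", "parental"), seed = 1L) {
  error_mode <- match.arg(error_mode)
  if (mean_depth <= 0) stopf("mean_depth must be > 0")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  set.seed(seed)
  allele_seq <- split(genome$alleles$sequence, genome$alleles$locus_id)
  allele_sym <- split(genome$alleles$allele, genome$alleles$locus_id)
  inds <- rownames(genotypes)
  loci <- colnames(genotypes)
  out <- vector("list", length(inds) * length(loci))
  k <- 0L
  for (j in seq_along(loci)) {
    lid <- loci[j]
    seqs <- allele_seq[[lid]]
    names(seqs) <- allele_sym[[lid]]
    depths <- rnbinom(length(inds), size = depth_dispersion, mu = mean_depth)
    for (i in seq_along(inds)) {
      n <- depths[i]
      if (n == 0L || is.na(genotypes[i, j])) next
      als <- strsplit(genotypes[i, j], "/", fixed = TRUE)[[1]]
      src <- sample(als, n, replace = TRUE)
      n_err <- rbinom(1L, n, error_rate)
      counts <- table(src)
      rows <- data.frame(individual_id = inds[i], locus_id = lid,
                         sequence = unname(seqs[names(counts)]),
                         depth = as.integer(counts))
      if (n_err > 0L) {
        err_src <- sample(src, n_err)
        err_seq <- vapply(err_src, function(a) {
          if (error_mode == "novel") mutate_seq(seqs[[a]], 1)
          else {
            others <- setdiff(als, a)
            if (length(others)) seqs[[sample(c(others, others), 1)]]
            else mutate_seq(seqs[[a]], 1)
          }
        }, character(1))
        # remove the error reads from their source-allele counts
        err_counts <- table(err_src)
        rows$depth <- rows$depth -
          as.integer(ifelse(is.na(err_counts[names(counts)]), 0L,
                            err_counts[names(counts)]))
        etab <- table(err_seq)
        rows <- rbind(rows[rows$depth > 0L, , drop = FALSE],
                      data.frame(individual_id = inds[i], locus_id = lid,
                                 sequence = names(etab),
                                 depth = as.integer(etab)))
      }
      k <- k + 1L
      out[[k]] <- rows
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(individual_id = character(), locus_id = character(),
               sequence = character(), depth = integer())
  rownames(res) <- NULL
  res
}
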