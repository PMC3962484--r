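#' Simulate one meiotic tetrad for a chromosome
#'
#' A tetrad is the four chromatids of a bivalent: chromatids 1 and 2 are
#' sisters carrying the centromere of maternal haplotype 1, chromatids 3 and
#' 4 sisters of haplotype 2.  Crossovers are placed per arm according to the
#' interference model, each crossover joins one chromatid of each homolog
#' chosen uniformly (no chromatid interference) and exchanges the segments
#' distal to the crossover point.  Meiosis I separates centromeres, so pole
#' one receives chromatids 1 and 2 and pole two receives 3 and 4.
#'
#' Interference models:
#' \describe{
#'   \item{complete}{exactly one crossover per arm, uniformly positioned —
#'     the near-complete interference typical of salmonid female meiosis.}
#'   \item{none}{Poisson crossover count with mean equal to the arm length in
#'     Morgans, uniform positions.}
#'   \item{gamma}{stationary gamma renewal process along the arm with shape
#'     \code{nu} (inter-crossover distances Gamma(nu, rate nu) in Morgans);
#'     \code{nu = 1} reduces to Poisson, large \code{nu} approaches evenly
#'     spaced crossovers.}
#' }
#'
#' @param genome a [build_genome()] result.
#' @param chrom chromosome id.
#' @param interference one of \code{"complete"}, \code{"none"},
#'   \code{"gamma"}.
#' @param nu gamma shape parameter (used when \code{interference = "gamma"}).
#' @param positions marker positions (cM) at which chromatid haplotypes are
#'   evaluated; defaults to the genome's loci on that chromosome.
#' @return a list with \code{haplotypes} (4 x n_markers integer matrix of
#'   maternal haplotype origin, 1 or 2), \code{positions} and
#'   \code{crossovers} (data.frame arm, pos, chromatid_1, chromatid_2).
#' @export
simulate_tetrad <- function(genome, chrom, interference = "complete",
                            nu = 10, positions = NULL) {
  ch <- genome$chromosomes[genome$chromosomes$chrom == chrom, ]
  if (nrow(ch) != 1L) stopf("unknown chromosome '%s'", chrom)
  if (is.null(positions))
    positions <- genome$loci$pos[genome$loci$chrom == chrom]
  cen <- ch$centromere
  H <- matrix(rep(c(1L, 1L, 2L, 2L), length(positions)), nrow = 4)
  xo <- list()
  for (arm in c("p", "q")) {
    arm_len <- if (arm == "p") ch$p_len else ch$q_len
    if (arm_len <= 0) next
    d <- crossover_distances(arm_len, interference, nu)
    if (!length(d)) next
    d <- sort(d)  # process from centromere outward
    for (u in d) {
      i <- sample.int(2L, 1L)          # chromatid of homolog 1
      j <- 2L + sample.int(2L, 1L)     # chromatid of homolog 2
      distal <- if (arm == "p") positions < cen - u else positions > cen + u
      tmp <- H[i, distal]
      H[i, distal] <- H[j, distal]
      H[j, distal] <- tmp
      xo[[length(xo) + 1L]] <- data.frame(arm = arm, dist_cen = u,
                                          chromatid_1 = i, chromatid_2 = j)
    }
  }
  crossovers <- if (length(xo)) do.call(rbind, xo) else
    data.frame(arm = character(), dist_cen = numeric(),
               chromatid_1 = integer(), chromatid_2 = integer())
  list(haplotypes = H, positions = positions, crossovers = crossovers)
}

#' Crossover distances from the centromere along one arm
#' @noRd
crossover_distances <- function(arm_len, interference, nu = 10) {
  L <- arm_len / 100  # Morgans
  switch(interference,
    complete = runif(1, 0, arm_len),
    none = {
      k <- rpois(1, L)
      if (k > 0) runif(k, 0, arm_len) else numeric()
    },
    gamma = {
      # stationary renewal: start the process well before the arm so the
      # first event on [0, L] follows the equilibrium delay distribution
      burn <- 10 + 5 / nu
      t <- -burn
      pts <- numeric()
      while (t < L) {
        t <- t + rgamma(1, shape = nu, rate = nu)
        if (t >= 0 && t < L) pts <- c(pts, t)
      }
      pts * 100
    },
    stopf("unknown interference model '%s'", interference))
}

#' Specify a mapping cross
#'
#' @param cross_type \code{"haploid"} (gynogenetic haploid: eggs activated
#'   with UV-inactivated milt, offspring carry one maternal chromatid),
#'   \code{"gynogenetic_diploid"} (second polar body retained by heat shock:
#'   offspring carry the two chromatids of one meiosis-I pole, a half
#'   tetrad) or \code{"diploid"} (one chromatid from each parent).
#' @param n_offspring number of offspring (>= 1).
#' @param interference,nu crossover interference model, see
#'   [simulate_tetrad()].
#' @param with_sire logical; a sire is only meaningful for diploid crosses
#'   and is rejected for gynogenetic types.
#' @param family_id label carried into output tables.
#' @return an object of class \code{cross_spec}.
#' @export
cross_spec <- function(cross_type = c("haploid", "gynogenetic_diploid",
                                      "diploid"),
                       n_offspring, interference = "complete", nu = 10,
                       with_sire = cross_type == "diploid",
                       family_id = "F1") {
  cross_type <- match.arg(cross_type)
  if (n_offspring < 1L) stopf("n_offspring must be >= 1")
  if (with_sire && cross_type != "diploid")
    stopf("a sire cannot be specified for a gynogenetic cross (%s)", cross_type)
  structure(list(cross_type = cross_type, n_offspring = as.integer(n_offspring),
                 interference = interference, nu = nu,
                 with_sire = with_sire, family_id = family_id),
            class = "cross_spec")
}

#' Simulate true genotypes for a cross
#'
#' One tetrad is simulated per offspring per chromosome.  Haploid offspring
#' receive one random chromatid; gynogenetic diploids receive both chromatids
#' of one randomly chosen meiosis-I pole (half-tetrad, so they are
#' heterozygous at a locus exactly when an odd exchange separates the two
#' pole chromatids there — i.e. when a crossover fell between locus and
#' centromere on a chromatid involved); diploid offspring receive one
#' maternal plus one paternal chromatid.
#'
#' Duplicated paralog pairs are additionally reported as a collapsed
#' composite locus (id = pair_id): in haploids the composite genotype is the
#' unordered pair of the two paralog alleles, reproducing the expected
#' segregation of duplicated RAD markers.
#'
#' @param genome a [build_genome()] result.
#' @param spec a [cross_spec()].
#' @param seed integer RNG seed.
#' @return list with \code{genotypes} (character matrix offspring x loci,
#'   entries \code{"a"} for a hemizygous haploid allele or \code{"a/b"}
#'   diploid genotypes), \code{composite} (offspring x paralog-pair matrix of
#'   collapsed duplicated-locus genotypes, or NULL), and \code{spec}.
#' @export
simulate_cross <- function(genome, spec, seed = 1L) {
  stopifnot(inherits(genome, "genome"), inherits(spec, "cross_spec"))
  set.seed(seed)
  loci <- genome$loci
  n_off <- spec$n_offspring
  G <- matrix(NA_character_, n_off, nrow(loci),
              dimnames = list(sprintf("%s_%03d", spec$family_id, seq_len(n_off)),
                              loci$locus_id))
  for (chrom in genome$chromosomes$chrom) {
    idx <- which(loci$chrom == chrom)
    if (!length(idx)) next
    pos <- loci$pos[idx]
    dam_alleles <- rbind(loci$dam_1[idx], loci$dam_2[idx])
    sire_alleles <- rbind(loci$sire_1[idx], loci$sire_2[idx])
    for (o in seq_len(n_off)) {
      tet <- simulate_tetrad(genome, chrom, spec$interference, spec$nu,
                             positions = pos)
      H <- tet$haplotypes
      if (spec$cross_type == "haploid") {
        k <- sample.int(4L, 1L)
        G[o, idx] <- dam_alleles[cbind(H[k, ], seq_along(idx))]
      } else if (spec$cross_type == "gynogenetic_diploid") {
        pole <- sample(c(0L, 2L), 1L)
        a1 <- dam_alleles[cbind(H[pole + 1L, ], seq_along(idx))]
        a2 <- dam_alleles[cbind(H[pole + 2L, ], seq_along(idx))]
        G[o, idx] <- geno_string(a1, a2)
      } else {
        k <- sample.int(4L, 1L)
        a1 <- dam_alleles[cbind(H[k, ], seq_along(idx))]
        tet2 <- simulate_tetrad(genome, chrom, spec$interference, spec$nu,
                                positions = pos)
        k2 <- sample.int(4L, 1L)
        a2 <- sire_alleles[cbind(tet2$haplotypes[k2, ], seq_along(idx))]
        G[o, idx] <- geno_string(a1, a2)
      }
    }
  }
  composite <- NULL
  pair_ids <- unique(loci$pair_id[loci$is_duplicated])
  pair_ids <- pair_ids[!is.na(pair_ids)]
  if (length(pair_ids) && spec$cross_type == "haploid") {
    composite <- matrix(NA_character_, n_off, length(pair_ids),
                        dimnames = list(rownames(G), pair_ids))
    for (pid in pair_ids) {
      members <- loci$locus_id[!is.na(loci$pair_id) & loci$pair_id == pid]
      composite[, pid] <- geno_string(G[, members[1]], G[, members[2]])
    }
  }
  list(genotypes = G, composite = composite, spec = spec)
}

#' Simulate an unrelated reference panel of diploid individuals
#'
#' Stands in for the population panel used to discover loci and build the
#' reference database: each individual draws two alleles per locus by
#' Hardy-Weinberg sampling with uniform allele frequencies over the locus's
#' allele set.
#'
#' @param genome a [build_genome()] result.
#' @param n_individuals panel size.
#' @param seed RNG seed.
#' @return character matrix individuals x loci of \code{"x/y"} genotypes.
#' @export
simulate_panel <- function(genome, n_individuals, seed = 1L) {
  set.seed(seed)
  loci <- genome$loci
  G <- matrix(NA_character_, n_individuals, nrow(loci),
              dimnames = list(sprintf("P_%03d", seq_len(n_individuals)),
                              loci$locus_id))
  for (i in seq_len(nrow(loci))) {
    al <- genome$alleles$allele[genome$alleles$locus_id == loci$locus_id[i]]
    a1 <- sample(al, n_individuals, replace = TRUE)
    a2 <- sample(al, n_individuals, replace = TRUE)
    G[, i] <- geno_string(a1, a2)
  }
  G
}
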