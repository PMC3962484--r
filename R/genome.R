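#' Karyotype and genome configuration
#'
#' A genome is described by its chromosomes (two arm lengths in cM, with the
#' centromere at the p/q junction), the homeologous arm pairs left by whole
#' genome duplication, and a table of marker loci.  Positions are in cM on a
#' per-chromosome coordinate whose origin is the p-arm terminus, so the
#' centromere sits at \code{p_len} and the chromosome ends at
#' \code{p_len + q_len}.  Acrocentric chromosomes have \code{p_len} zero or
#' near zero.
#'
#' @param chromosomes data.frame with columns \code{chrom} (integer id),
#'   \code{p_len}, \code{q_len} (cM, \code{p_len <= q_len}, \code{q_len > 0}).
#' @param homeolog_pairs optional data.frame with columns \code{pair_id},
#'   \code{chrom_a}, \code{arm_a}, \code{chrom_b}, \code{arm_b},
#'   \code{divergence} (1-3 mismatches between paralog alleles).
#' @param loci data.frame of marker loci as produced by [place_loci()], with
#'   columns \code{locus_id}, \code{chrom}, \code{pos}, \code{is_duplicated},
#'   \code{pair_id}, \code{dup_class}.
#' @param seed integer RNG seed controlling sequence and allele generation.
#' @return an object of class \code{genome_config}.
#' @seealso [build_genome()], [chinook_karyotype()], [place_loci()]
#' @export
genome_config <- function(chromosomes, homeolog_pairs = NULL, loci = NULL,
                          seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "p_len", "q_len") %in% names(chromosomes)))
  if (any(chromosomes$q_len <= 0)) stopf("q arm lengths must be positive")
  if (any(chromosomes$p_len < 0)) stopf("p arm lengths must be nonnegative")
  if (any(chromosomes$p_len > chromosomes$q_len))
    stopf("p arm must not exceed q arm (p <= q convention)")
  chromosomes$type <- ifelse(chromosomes$p_len < 0.1 * chromosomes$q_len,
                             "acrocentric", "metacentric")
  chromosomes$centromere <- chromosomes$p_len
  chromosomes$length <- chromosomes$p_len + chromosomes$q_len
  if (!is.null(homeolog_pairs)) {
    need <- c("pair_id", "chrom_a", "arm_a", "chrom_b", "arm_b", "divergence")
    stopifnot(all(need %in% names(homeolog_pairs)))
    if (!all(homeolog_pairs$divergence %in% 1:3))
      stopf("homeolog divergence must be 1, 2 or 3 mismatches")
    ok <- homeolog_pairs$chrom_a %in% chromosomes$chrom &
      homeolog_pairs$chrom_b %in% chromosomes$chrom
    if (!all(ok)) stopf("homeolog pair references unknown chromosome")
  }
  structure(list(chromosomes = chromosomes,
                 homeolog_pairs = homeolog_pairs,
                 loci = loci, seed = as.integer(seed)),
            class = "genome_config")
}

#' The 34-chromosome Chinook-type karyotype
#'
#' Sixteen metacentric plus eighteen acrocentric chromosomes, the karyotype
#' of Chinook salmon.  Arm lengths are physical-scale placeholders in cM used
#' to position markers; under complete crossover interference every arm maps
#' to 50 cM of genetic length regardless of these values.
#'
#' @param n_metacentric,n_acrocentric chromosome counts (defaults 16 and 18).
#' @param p_met,q_met metacentric arm lengths (cM).
#' @param q_acro acrocentric q-arm length (cM).
#' @param p_acro acrocentric p-arm length (cM); 0 gives a strictly telocentric
#'   model, a small positive value emulates the short p arms seen on a few
#'   acrocentric chromosomes.
#' @return a chromosome data.frame suitable for [genome_config()].
#' @export
chinook_karyotype <- function(n_metacentric = 16L, n_acrocentric = 18L,
                              p_met = 50, q_met = 60, q_acro = 80,
                              p_acro = 0) {
  n <- n_metacentric + n_acrocentric
  data.frame(
    chrom = seq_len(n),
    p_len = c(rep(p_met, n_metacentric), rep(p_acro, n_acrocentric)),
    q_len = c(rep(q_met, n_metacentric), rep(q_acro, n_acrocentric))
  )
}

#' Place marker loci on a karyotype
#'
#' Non-duplicated loci are spread evenly (with small jitter) along each
#' chromosome.  Duplicated loci are laid down as paralog pairs on the two
#' arms of each homeolog pair, confined to the distal portion of the arm
#' (whole-genome-duplication residual tetrasomy keeps distal homeologous
#' regions similar, so that is where duplicated loci concentrate).
#'
#' @param chromosomes chromosome table (see [genome_config()]).
#' @param homeolog_pairs homeolog pair table, or NULL for none.
#' @param n_per_chrom non-duplicated loci per chromosome.
#' @param n_dup_per_pair paralog pairs per homeolog arm pair.
#' @param dup_distal_frac duplicated loci are placed in the distal
#'   \code{1 - dup_distal_frac} fraction of the arm (default: distal 30\%).
#' @param dup_classes named probability vector over duplicated-marker classes
#'   \code{OPP_aa_ab}, \code{OPP_aa_bc}, \code{BPP_ab_ac}, \code{BPP_ab_cd},
#'   \code{aa_bb}, \code{ab_ab}.
#' @param seed RNG seed for placement.
#' @return loci data.frame for [genome_config()].
#' @export
place_loci <- function(chromosomes, homeolog_pairs = NULL,
                       n_per_chrom = 10L, n_dup_per_pair = 0L,
                       dup_distal_frac = 0.7,
                       dup_classes = c(OPP_aa_ab = 0.35, OPP_aa_bc = 0.15,
                                       BPP_ab_ac = 0.25, BPP_ab_cd = 0.15,
                                       aa_bb = 0.05, ab_ab = 0.05),
                       seed = 1L) {
  set.seed(seed)
  chromosomes$length <- chromosomes$p_len + chromosomes$q_len
  out <- list()
  for (i in seq_len(nrow(chromosomes))) {
    ch <- chromosomes[i, ]
    # evenly spaced quantiles with jitter keeps coverage of both arm ends
    frac <- (seq_len(n_per_chrom) - 0.5) / n_per_chrom
    frac <- pmin(1, pmax(0, frac + runif(n_per_chrom, -0.4, 0.4) / n_per_chrom))
    out[[i]] <- data.frame(
      locus_id = sprintf("L%02d_%03d", ch$chrom, seq_len(n_per_chrom)),
      chrom = ch$chrom, pos = sort(frac * ch$length),
      is_duplicated = FALSE, pair_id = NA_character_,
      dup_class = NA_character_, paralog = NA_integer_
    )
  }
  loci <- do.call(rbind, out)
  if (!is.null(homeolog_pairs) && n_dup_per_pair > 0L) {
    dup <- list()
    for (i in seq_len(nrow(homeolog_pairs))) {
      hp <- homeolog_pairs[i, ]
      cls <- sample(names(dup_classes), n_dup_per_pair, replace = TRUE,
                    prob = dup_classes)
      for (j in seq_len(n_dup_per_pair)) {
        pid <- sprintf("%s_d%02d", hp$pair_id, j)
        pos_a <- arm_position(chromosomes, hp$chrom_a, hp$arm_a,
                              runif(1, dup_distal_frac, 1))
        pos_b <- arm_position(chromosomes, hp$chrom_b, hp$arm_b,
                              runif(1, dup_distal_frac, 1))
        dup[[length(dup) + 1L]] <- data.frame(
          locus_id = paste0(pid, c("_p1", "_p2")),
          chrom = c(hp$chrom_a, hp$chrom_b), pos = c(pos_a, pos_b),
          is_duplicated = TRUE, pair_id = pid, dup_class = cls[j],
          paralog = 1:2
        )
      }
    }
    loci <- rbind(loci, do.call(rbind, dup))
  }
  loci[order(loci$chrom, loci$pos), ]
}

#' Convert an arm fraction to a chromosome coordinate
#'
#' Fraction 0 is the centromere, fraction 1 the arm terminus.
#' @noRd
arm_position <- function(chromosomes, chrom, arm, frac) {
  ch <- chromosomes[chromosomes$chrom == chrom, ]
  if (arm == "p") ch$p_len * (1 - frac) else ch$p_len + frac * ch$q_len
}

#' Instantiate a genome: sequences, alleles, parental genotypes
#'
#' Given a validated configuration, draws a 74-nt consensus sequence per
#' locus and an allele table mapping the per-locus allele symbols (a, b, c,
#' d) to concrete sequences.  Variant alleles of non-duplicated loci differ
#' from the reference allele at one site; variant alleles of duplicated loci
#' differ at \code{divergence} sites of their homeolog pair, using disjoint
#' site sets so every allele stays within the 3-mismatch collapse radius of
#' the locus consensus.  Parental genotypes are assigned from the
#' duplicated-marker class (paralog pairs) or as dam-heterozygous /
#' sire-heterozygous (unique loci), making every unique locus informative in
#' maternal crosses.
#'
#' @param config a [genome_config()].
#' @return an object of class \code{genome} with elements \code{chromosomes},
#'   \code{homeolog_pairs}, \code{loci} (now carrying \code{sequence},
#'   \code{dam_1}, \code{dam_2}, \code{sire_1}, \code{sire_2}) and
#'   \code{alleles} (locus_id, allele, sequence).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  loci <- config$loci
  if (is.null(loci) || nrow(loci) == 0L) {
    loci <- data.frame(locus_id = character(), chrom = integer(),
                       pos = numeric(), is_duplicated = logical(),
                       pair_id = character(), dup_class = character(),
                       paralog = integer())
  }
  chrom_tab <- config$chromosomes
  bad_pos <- !is.na(loci$pos) &
    (loci$pos < 0 | loci$pos > chrom_tab$length[match(loci$chrom, chrom_tab$chrom)])
  if (any(bad_pos)) stopf("locus position outside chromosome: %s",
                          paste(loci$locus_id[bad_pos], collapse = ", "))
  if (any(loci$is_duplicated)) {
    if (is.null(config$homeolog_pairs))
      stopf("duplicated loci declared but no homeolog_pairs configured")
    check_paralog_arms(loci, chrom_tab, config$homeolog_pairs)
  }
  set.seed(config$seed)
  alleles <- list()
  geno <- matrix(NA_character_, nrow(loci), 4,
                 dimnames = list(NULL, c("dam_1", "dam_2", "sire_1", "sire_2")))
  loci$sequence <- rep(NA_character_, nrow(loci))
  done_pairs <- character()
  for (i in seq_len(nrow(loci))) {
    if (!loci$is_duplicated[i]) {
      cons <- random_seq(1)
      alt <- mutate_seq(cons, 1)
      loci$sequence[i] <- cons
      alleles[[length(alleles) + 1L]] <- data.frame(
        locus_id = loci$locus_id[i], allele = c("a", "b"),
        sequence = c(cons, alt))
      geno[i, ] <- c("a", "b", "a", "b")
    } else if (!(loci$pair_id[i] %in% done_pairs)) {
      idx <- which(loci$pair_id == loci$pair_id[i])
      idx <- idx[order(loci$paralog[idx])]
      hp_id <- sub("_d[0-9]+$", "", loci$pair_id[i])
      d <- config$homeolog_pairs$divergence[
        match(hp_id, config$homeolog_pairs$pair_id)]
      pairgen <- dup_pair_alleles(loci$dup_class[i], d)
      for (k in 1:2) {
        loci$sequence[idx[k]] <- pairgen$sequences[[pairgen$dam[[k]][1]]]
        geno[idx[k], 1:2] <- pairgen$dam[[k]]
        geno[idx[k], 3:4] <- pairgen$dam[[k]]  # maternal crosses; sire unused
        alleles[[length(alleles) + 1L]] <- data.frame(
          locus_id = loci$locus_id[idx[k]],
          allele = names(pairgen$sequences),
          sequence = unname(unlist(pairgen$sequences)))
      }
      done_pairs <- c(done_pairs, loci$pair_id[i])
    }
  }
  allele_tab <- if (length(alleles)) do.call(rbind, alleles) else
    data.frame(locus_id = character(), allele = character(),
               sequence = character())
  if (any(nchar(allele_tab$sequence) != 74L))
    stopf("internal error: allele sequence not 74 nt")
  loci <- cbind(loci, as.data.frame(geno))
  structure(list(chromosomes = chrom_tab,
                 homeolog_pairs = config$homeolog_pairs,
                 loci = loci, alleles = allele_tab,
                 seed = config$seed),
            class = "genome")
}

#' @noRd
check_paralog_arms <- function(loci, chrom_tab, hp) {
  dup <- loci[loci$is_duplicated, ]
  for (pid in unique(dup$pair_id)) {
    members <- dup[dup$pair_id == pid, ]
    if (nrow(members) != 2L)
      stopf("paralog pair %s must have exactly 2 members", pid)
    hp_id <- sub("_d[0-9]+$", "", pid)
    row <- hp[hp$pair_id == hp_id, ]
    if (nrow(row) != 1L)
      stopf("paralog pair %s does not match a configured homeolog pair", pid)
    arms <- vapply(seq_len(2), function(k) {
      cen <- chrom_tab$centromere[match(members$chrom[k], chrom_tab$chrom)]
      if (members$pos[k] <= cen) "p" else "q"
    }, character(1))
    want <- data.frame(chrom = c(row$chrom_a, row$chrom_b),
                       arm = c(row$arm_a, row$arm_b))
    got <- data.frame(chrom = members$chrom, arm = arms)
    ok <- (identical(got$chrom, want$chrom) && identical(got$arm, want$arm)) ||
      (identical(got$chrom, rev(want$chrom)) && identical(got$arm, rev(want$arm)))
    if (!ok)
      stopf("paralog pair %s sits on arms not declared in homeolog_pairs", pid)
  }
  invisible(TRUE)
}

#' Allele sequences and parental genotypes for one duplicated-marker class
#'
#' Symbols are shared across the two paralogs (a collapsed duplicated locus
#' is scored on observed sequence identity).  Variant symbols b, c, d sit at
#' Hamming distance \code{divergence} from a on disjoint site sets.
#' @noRd
dup_pair_alleles <- function(dup_class, divergence) {
  cls <- switch(dup_class,
    aa_bb     = list(c("a", "a"), c("b", "b")),
    ab_ab     = list(c("a", "b"), c("a", "b")),
    OPP_aa_ab = list(c("a", "a"), c("a", "b")),
    OPP_aa_bc = list(c("a", "a"), c("b", "c")),
    BPP_ab_ac = list(c("a", "b"), c("a", "c")),
    BPP_ab_cd = list(c("a", "b"), c("c", "d")),
    stopf("unknown duplicated-marker class '%s'", dup_class))
  symbols <- sort(unique(unlist(cls)))
  base <- random_seq(1)
  pos_pool <- sample(74L, 3L * divergence)
  seqs <- list(a = base)
  extra <- setdiff(symbols, "a")
  for (k in seq_along(extra)) {
    pos <- pos_pool[((k - 1L) * divergence + 1L):(k * divergence)]
    seqs[[extra[k]]] <- mutate_seq(base, divergence, positions = pos)
  }
  list(sequences = seqs[symbols], dam = cls)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d chromosomes (%d metacentric, %d acrocentric), %d loci (%d duplicated)\n",
              nrow(x$chromosomes),
              sum(x$chromosomes$type == "metacentric"),
              sum(x$chromosomes$type == "acrocentric"),
              nrow(x$loci), sum(x$loci$is_duplicated)))
  invisible(x)
}
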