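#' Assign pileup reads to reference-database loci
#'
#' Each distinct read sequence is compared against every retained database
#' consensus; it is assigned when exactly one locus lies within
#' \code{max_mismatch}.  Reads matching several loci cannot be relied upon
#' and are dropped (counted in the \code{dropped_multi} attribute); reads
#' matching none are unassigned (\code{dropped_none}).
#'
#' @param pileups pileup data.frame (\code{individual_id}, \code{sequence},
#'   \code{depth}).
#' @param db refdb data.frame; only loci whose status is not
#'   \code{excluded_*} are alignment targets.
#' @param params a [screening_params()].
#' @return data.frame (\code{individual_id}, \code{locus_id},
#'   \code{sequence}, \code{depth}) of assigned reads, with drop counts as
#'   attributes.
#' @export
align_to_db <- function(pileups, db, params = screening_params()) {
  keep <- !startsWith(db$status, "excluded")
  targets <- db[keep, , drop = FALSE]
  seqs <- unique(pileups$sequence)
  if (!nrow(targets) || !length(seqs)) {
    out <- pileups[0, c("individual_id", "sequence", "depth")]
    out$locus_id <- character()
    return(out)
  }
  D <- hamming_matrix(seqs, targets$sequence)
  hits <- D <= params$max_mismatch
  n_hits <- rowSums(hits)
  assign_idx <- ifelse(n_hits == 1L, max.col(hits, ties.method = "first"),
                       NA_integer_)
  locus_of <- targets$locus_id[assign_idx[match(pileups$sequence, seqs)]]
  out <- data.frame(individual_id = pileups$individual_id,
                    locus_id = locus_of,
                    sequence = pileups$sequence,
                    depth = pileups$depth)
  res <- out[!is.na(out$locus_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_multi") <- sum(pileups$depth[
    n_hits[match(pileups$sequence, seqs)] > 1L])
  attr(res, "dropped_none") <- sum(pileups$depth[
    n_hits[match(pileups$sequence, seqs)] == 0L])
  res
}

#' Call one genotype from per-allele read depths
#'
#' Depth rules for RAD genotypes in crosses where allele depth can be
#' unbalanced: a locus with total depth below \code{min_reads_for_genotype}
#' is missing; an allele is \emph{verified} when its depth exceeds two; a
#' heterozygote is called when exactly two verified alleles are present and
#' total depth is at least 10; one verified allele gives a homozygote for
#' the majority allele (the unverified minor depth is consistent with
#' sequencing error); three or more verified alleles are aberrant (possible
#' paralog collapse) and the call is missing.
#'
#' @param depths named numeric vector of per-allele read depths.
#' @param params a [screening_params()].
#' @return a genotype string \code{"x/x"} or \code{"x/y"} (names sorted), or
#'   NA for missing/aberrant.
#' @export
call_genotype <- function(depths, params = screening_params()) {
  depths <- depths[depths > 0]
  total <- sum(depths)
  if (total < params$min_reads_for_genotype) return(NA_character_)
  verified <- names(depths)[depths > 2]
  if (length(verified) >= 3L) return(NA_character_)   # aberrant
  if (length(verified) == 2L) return(geno_string(verified[1], verified[2]))
  if (length(verified) == 1L) return(geno_string(verified, verified))
  NA_character_
}

#' Call a genotype matrix from assigned pileups
#'
#' Within each locus, observed sequences are renamed to allele symbols a, b,
#' c, ... in order of decreasing total depth (ties broken lexicographically)
#' so symbols are stable across individuals; the sequence behind each symbol
#' is kept in the \code{allele_key} attribute.
#'
#' @param assigned output of [align_to_db()].
#' @param params a [screening_params()].
#' @return character matrix individuals x loci of genotype strings/NA.
#' @export
call_genotype_matrix <- function(assigned, params = screening_params()) {
  inds <- sort(unique(assigned$individual_id))
  loci <- sort(unique(assigned$locus_id))
  M <- matrix(NA_character_, length(inds), length(loci),
              dimnames = list(inds, loci))
  key <- list()
  for (lid in loci) {
    sub <- assigned[assigned$locus_id == lid, , drop = FALSE]
    tot <- tapply(sub$depth, sub$sequence, sum)
    ord <- order(-tot, names(tot))
    symbols <- letters[seq_along(ord)]
    names(symbols) <- names(tot)[ord]
    key[[lid]] <- symbols
    for (ind in unique(sub$individual_id)) {
      rows <- sub[sub$individual_id == ind, ]
      d <- tapply(rows$depth, symbols[rows$sequence], sum)
      M[ind, lid] <- call_genotype(d, params)
    }
  }
  attr(M, "allele_key") <- key
  M
}

#' Classify a duplicated marker from its parental paralog genotypes
#'
#' The two paralogs of a duplicated RAD locus are scored jointly as one
#' locus, so the expected offspring segregation in a haploid cross follows
#' from enumerating the four equally likely combinations of maternal gametes
#' across the two paralogs.  Classes: both paralogs fixed for different
#' alleles (\code{aa_bb}) or heterozygous for the same pair (\code{ab_ab})
#' are unmappable; one paralog polymorphic (OPP) maps that paralog; both
#' paralogs polymorphic for different pairs (BPP) maps both.
#'
#' @param paralog1,paralog2 two-character parental genotypes of the paralogs
#'   (e.g. \code{"aa"}, \code{"ab"}).
#' @return list with \code{class}, \code{mappable} (integer vector of
#'   paralog indices), and \code{expected} (named probability vector over
#'   composite offspring genotypes, computed by gamete enumeration).
#' @export
classify_duplicate_marker <- function(paralog1, paralog2) {
  g1 <- strsplit(paralog1, "")[[1]]
  g2 <- strsplit(paralog2, "")[[1]]
  if (length(g1) != 2L || length(g2) != 2L)
    return(list(class = "unclassified", mappable = integer(),
                expected = NULL))
  expected <- enumerate_composite_gametes(g1, g2)
  het1 <- g1[1] != g1[2]
  het2 <- g2[1] != g2[2]
  shared <- length(intersect(unique(g1), unique(g2)))
  cls <- if (!het1 && !het2) {
    if (shared == 1L) "monomorphic" else "unmappable_aa_bb"
  } else if (het1 && het2) {
    if (shared == 2L) "unmappable_ab_ab"
    else if (shared == 1L) "BPP_ab_ac" else "BPP_ab_cd"
  } else {
    if (shared >= 1L) "OPP_aa_ab" else "OPP_aa_bc"
  }
  mappable <- switch(substr(cls, 1, 3),
                     OPP = which(c(het1, het2)),
                     BPP = 1:2,
                     integer())
  list(class = cls, mappable = mappable, expected = expected)
}

#' Expected composite-genotype frequencies by maternal gamete enumeration
#'
#' Paralogs segregate independently (they sit on different homeologous
#' arms); each maternal gamete carries one allele of each paralog, and the
#' composite genotype observed at the collapsed locus is the unordered
#' allele pair.
#' @noRd
enumerate_composite_gametes <- function(g1, g2) {
  combos <- expand.grid(a1 = g1, a2 = g2, stringsAsFactors = FALSE)
  comp <- geno_string(combos$a1, combos$a2)
  tab <- table(comp) / nrow(combos)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Goodness-of-fit check of observed segregation against class expectation
#'
#' Chi-square statistic over the expected genotype classes; genotypes not in
#' the expectation at all are model violations and fail the check outright.
#'
#' @param calls character vector of offspring genotype strings (NA =
#'   unscored), or a named table of counts.
#' @param expected named probability vector (e.g. from
#'   [classify_duplicate_marker()]).
#' @param alpha significance level for the pass/fail flag.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{pass}, \code{n} and \code{unexpected} (count of off-model
#'   genotypes).
#' @export
segregation_check <- function(calls, expected, alpha = 0.05) {
  counts <- if (is.table(calls) || (!is.null(names(calls)) && is.numeric(calls))) {
    calls
  } else {
    table(calls[!is.na(calls)])
  }
  n <- sum(counts)
  if (n == 0) stopf("no scored offspring")
  if (n < 10) warning("fewer than 10 scored offspring; check is unreliable")
  unexpected <- sum(counts[!(names(counts) %in% names(expected))])
  obs <- as.numeric(counts[names(expected)])
  obs[is.na(obs)] <- 0
  e <- expected * (n - unexpected)
  if (unexpected > 0) {
    return(list(statistic = Inf, df = length(expected) - 1L, p_value = 0,
                pass = FALSE, n = n, unexpected = unexpected))
  }
  stat <- sum((obs - e)^2 / e)
  df <- length(expected) - 1L
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, pass = p >= alpha,
       n = n, unexpected = 0L)
}

#' Infer the duplicated-marker class from offspring composite genotypes
#'
#' The class of a duplicated locus (and hence the parental paralog
#' genotypes) can be read off the observed segregation: the set of
#' composite genotype classes in the haploid offspring identifies the
#' pattern of Table-style duplicated-marker segregation, and each composite
#' genotype then decomposes uniquely into one allele per paralog.  Mappable
#' paralogs yield decomposed haploid marker columns usable for linkage
#' mapping (and, for BPP loci, homeology inference).
#'
#' @param composite_calls character vector of composite genotype strings
#'   (\code{"x/y"}; NA = unscored) for the haploid offspring of one family.
#' @return list with \code{class}, \code{paralog_genotypes} (two-character
#'   strings in observed allele letters, NA when unmappable), and
#'   \code{decomposed} (matrix offspring x mappable paralogs with columns
#'   \code{p1}/\code{p2}, or NULL).
#' @export
infer_duplicate_marker <- function(composite_calls) {
  obs <- composite_calls[!is.na(composite_calls)]
  unclass_res <- list(class = "unclassified", paralog_genotypes = c(NA, NA),
                      decomposed = NULL)
  if (!length(obs)) return(unclass_res)
  cls <- sort(unique(obs))
  pairs <- strsplit(cls, "/", fixed = TRUE)
  letters_seen <- sort(unique(unlist(pairs)))
  hom <- cls[vapply(pairs, function(p) p[1] == p[2], logical(1))]
  het <- setdiff(cls, hom)
  n_let <- length(letters_seen)
  decompose <- function(sets) {
    # sets: list(p1 alleles, p2 alleles); map each call to (p1, p2)
    d <- t(vapply(composite_calls, function(g) {
      if (is.na(g)) return(c(NA_character_, NA_character_))
      al <- strsplit(g, "/", fixed = TRUE)[[1]]
      a1 <- intersect(al, sets[[1]])
      a2 <- intersect(al, sets[[2]])
      # a shared allele can serve either paralog; resolve by elimination
      if (length(a1) == 2L) a1 <- setdiff(a1, a2)
      if (length(a2) == 2L) a2 <- setdiff(a2, a1)
      if (length(a1) != 1L || length(a2) != 1L)
        return(c(NA_character_, NA_character_))
      c(a1, a2)
    }, character(2)))
    colnames(d) <- c("p1", "p2")
    rownames(d) <- names(composite_calls)
    d
  }
  if (n_let == 2L) {
    a <- letters_seen[1]; b <- letters_seen[2]
    if (length(het) == 1L && !length(hom)) {
      return(list(class = "unmappable_aa_bb",
                  paralog_genotypes = c(paste0(a, a), paste0(b, b)),
                  decomposed = NULL))
    }
    if (length(hom) == 2L) {
      return(list(class = "unmappable_ab_ab",
                  paralog_genotypes = c(paste0(a, b), paste0(a, b)),
                  decomposed = NULL))
    }
    if (length(hom) == 1L && length(het) == 1L) {
      h <- strsplit(hom, "/", fixed = TRUE)[[1]][1]
      o <- setdiff(letters_seen, h)
      d <- decompose(list(h, c(h, o)))
      return(list(class = "OPP_aa_ab",
                  paralog_genotypes = c(paste0(h, h), paste0(h, o)),
                  decomposed = d[, "p2", drop = FALSE]))
    }
    return(unclass_res)
  }
  if (n_let == 3L) {
    shared <- letters_seen[vapply(letters_seen, function(l)
      sum(vapply(pairs, function(p) l %in% p, logical(1))), integer(1)) >= 2L]
    if (!length(hom) && length(het) == 2L && length(shared) >= 1L) {
      s <- shared[1]
      others <- sort(setdiff(letters_seen, s))
      d <- decompose(list(s, others))
      return(list(class = "OPP_aa_bc",
                  paralog_genotypes = c(paste0(s, s),
                                        paste0(others[1], others[2])),
                  decomposed = d[, "p2", drop = FALSE]))
    }
    if (length(hom) == 1L) {
      s <- strsplit(hom, "/", fixed = TRUE)[[1]][1]
      others <- sort(setdiff(letters_seen, s))
      d <- decompose(list(c(s, others[1]), c(s, others[2])))
      return(list(class = "BPP_ab_ac",
                  paralog_genotypes = c(paste0(s, others[1]),
                                        paste0(s, others[2])),
                  decomposed = d))
    }
    return(unclass_res)
  }
  if (n_let == 4L) {
    # alleles of the same paralog never co-occur in a composite genotype
    a0 <- letters_seen[1]
    partners <- unique(unlist(lapply(pairs, function(p)
      if (a0 %in% p) setdiff(p, a0))))
    set1 <- sort(setdiff(letters_seen, partners))
    set2 <- sort(partners)
    if (length(set1) != 2L || length(set2) != 2L) return(unclass_res)
    d <- decompose(list(set1, set2))
    return(list(class = "BPP_ab_cd",
                paralog_genotypes = c(paste0(set1[1], set1[2]),
                                      paste0(set2[1], set2[2])),
                decomposed = d))
  }
  unclass_res
}
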