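#' Pairwise Hamming distances between two sets of equal-length sequences
#'
#' Whole-locus k-mismatch comparison is the matching primitive used
#' throughout the pipeline (locus clustering, self-alignment screening,
#' read-to-database assignment, cross-database alignment).  Distances are
#' computed as an indicator-matrix product: for each base b, the match count
#' between sequence i and j accumulates \code{Ia_b \%*\% t(Ib_b)}, and the
#' Hamming distance is the sequence length minus the total match count.
#'
#' @param a,b character vectors of sequences, all the same length.
#' @return an integer matrix of dimension \code{length(a) x length(b)}.
#' @examples
#' hamming_matrix(c("ACGT", "ACGA"), c("ACGT", "TCGA"))
#' @export
hamming_matrix <- function(a, b = a) {
  la <- unique(nchar(a)); lb <- unique(nchar(b))
  if (length(la) != 1L || length(lb) != 1L || la != lb)
    stopf("all sequences must share one length (got %s vs %s)",
          paste(la, collapse = ","), paste(lb, collapse = ","))
  w <- la
  ma <- seq_to_matrix(a)
  mb <- if (identical(a, b)) ma else seq_to_matrix(b)
  match_count <- matrix(0, nrow(ma), nrow(mb))
  for (base in c("A", "C", "G", "T")) {
    ia <- ma == base
    ib <- mb == base
    match_count <- match_count + ia %*% t(ib)
  }
  d <- w - match_count
  storage.mode(d) <- "integer"
  dimnames(d) <- list(names(a), names(b))
  d
}

#' @noRd
seq_to_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Draw uniform-random DNA sequences
#'
#' @param n number of sequences.
#' @param width sequence length in nucleotides (default 74, the RAD locus
#'   length used throughout).
#' @return character vector of length \code{n}.
#' @export
random_seq <- function(n, width = 74L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

#' Mutate a sequence at k distinct random positions
#'
#' Each chosen position is replaced by a different base, so the returned
#' sequence is at Hamming distance exactly \code{k} from the input.
#'
#' @param seq a sequence.
#' @param k number of substitutions.
#' @param positions optional fixed positions (length \code{k}).
#' @return the mutated sequence.
#' @export
mutate_seq <- function(seq, k, positions = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(positions)) positions <- sample(length(chars), k)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Majority-rule consensus of equal-length sequences
#'
#' Ties at a position are broken by lexicographic base order (A < C < G < T)
#' so the consensus is deterministic.
#'
#' @param seqs character vector of equal-length sequences.
#' @param weights optional nonnegative weights (e.g. read depths).
#' @return a single consensus sequence.
#' @export
consensus_seq <- function(seqs, weights = NULL) {
  if (length(seqs) == 1L) return(seqs)
  m <- seq_to_matrix(seqs)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  apply_cols <- vapply(seq_len(ncol(m)), function(j) {
    tab <- tapply(weights, m[, j], sum)
    # names(tab) sorted alphabetically: which.max takes the first maximum,
    # giving the lexicographically smallest base on ties
    names(tab)[which.max(tab)]
  }, character(1))
  paste(apply_cols, collapse = "")
}
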