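#' Write a reference database as FASTA with status tags
#'
#' Headers carry \code{status=} (and optional \code{reason=}) as key=value
#' tags after the locus id, with a TSV sidecar holding the full table.
#'
#' @param db refdb data.frame (\code{locus_id}, \code{sequence},
#'   \code{status}, ...).
#' @param path FASTA output path; the sidecar gets extension \code{.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_refdb_fasta <- function(db, path) {
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- sprintf("%s status=%s", db$locus_id, db$status)
  Biostrings::writeXStringSet(seqs, path)
  write_tsv(db, paste0(tools::file_path_sans_ext(path), ".tsv"))
  invisible(path)
}

#' Read a reference database written by [write_refdb_fasta()]
#'
#' @param path FASTA path.
#' @return refdb data.frame (\code{locus_id}, \code{sequence},
#'   \code{status}).
#' @export
read_refdb_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(seqs), " ", fixed = TRUE)
  status <- vapply(hdr, function(h) {
    tag <- grep("^status=", h, value = TRUE)
    if (length(tag)) sub("^status=", "", tag[1]) else NA_character_
  }, character(1))
  data.frame(locus_id = vapply(hdr, `[`, "", 1),
             sequence = as.character(seqs),
             status = status)
}

#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write a genotype matrix as TSV
#'
#' Rows are individuals, columns loci; missing calls are written as
#' \code{"-"}.
#' @param m character matrix of genotype strings.
#' @param path output path.
#' @export
write_genotype_tsv <- function(m, path) {
  out <- cbind(individual_id = rownames(m), as.data.frame(m))
  out[is.na(out)] <- "-"
  write_tsv(out, path)
}

#' Read a genotype matrix written by [write_genotype_tsv()]
#' @param path TSV path.
#' @return character matrix with \code{"-"} restored to NA.
#' @export
read_genotype_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual_id
  m[m == "-"] <- NA_character_
  m
}
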