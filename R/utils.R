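#' @keywords internal
"_PACKAGE"

#' Derive a child RNG seed from a global seed
#'
#' Pipeline stages draw their own seeds from one global seed by a fixed
#' affine map modulo 2^31 - 1, so any stage can be rerun independently of
#' the others with identical results.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0) or stage name (hashed to an index).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 1000L
  }
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + as.numeric(stage) * 9349 + 1) %% m
  as.integer(max(1, x))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Sort the two alleles of a genotype into a canonical string
#' @noRd
geno_string <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

#' @noRd
is_het_geno <- function(g) {
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(p) length(p) == 2L && p[1] != p[2], logical(1))
}
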