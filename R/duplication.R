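#' Kernel-smoothed proportion of duplicated loci along linkage groups
#'
#' Map positions are not uniformly distributed, so the local proportion of
#' duplicated markers is estimated by Nadaraya-Watson smoothing with a
#' Gaussian kernel (default bandwidth 2 cM) on a regular grid.
#'
#' @param map map data.frame with columns \code{group}, \code{marker},
#'   \code{position} and logical \code{is_duplicated}.
#' @param bandwidth kernel bandwidth in cM (> 0; default 2).
#' @param step grid step in cM (default 0.5).
#' @return data.frame \code{group}, \code{position}, \code{proportion}.
#' @export
duplicate_density <- function(map, bandwidth = 2, step = 0.5) {
  if (bandwidth <= 0) stopf("bandwidth must be positive")
  out <- lapply(unique(map$group), function(grp) {
    sub <- map[map$group == grp, , drop = FALSE]
    grid <- seq(0, max(sub$position), by = step)
    prop <- vapply(grid, function(x) {
      w <- stats::dnorm((x - sub$position) / bandwidth)
      if (sum(w) == 0) return(NA_real_)
      sum(w * sub$is_duplicated) / sum(w)
    }, numeric(1))
    data.frame(group = grp, position = grid, proportion = prop)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Infer homeologous arm pairs from mapped BPP paralog pairs
#'
#' A duplicated locus with both paralogs polymorphic (BPP) places each
#' paralog on its own arm; tallying the arm pairs linked by such paralog
#' pairs reveals which chromosome arms are homeologous.  Pairs whose two
#' paralogs land on the same arm are anomalous and excluded from the calls.
#'
#' @param bpp_pairs data.frame \code{pair_id}, \code{marker_1},
#'   \code{marker_2} (mapped paralog marker ids).
#' @param marker_arms data.frame \code{marker}, \code{arm} (arm label, e.g.
#'   \code{"chr3:q"}); every paralog marker must appear.
#' @param min_support minimum supporting pairs for a call (default 1).
#' @return data.frame \code{arm_a}, \code{arm_b} (\code{arm_a < arm_b}),
#'   \code{support}, sorted by decreasing support; anomalous same-arm pairs
#'   in the \code{anomalous} attribute.
#' @export
infer_homeologies <- function(bpp_pairs, marker_arms, min_support = 1L) {
  empty <- data.frame(arm_a = character(), arm_b = character(),
                      support = integer())
  if (!nrow(bpp_pairs)) {
    attr(empty, "anomalous") <- character()
    return(empty)
  }
  a1 <- marker_arms$arm[match(bpp_pairs$marker_1, marker_arms$marker)]
  a2 <- marker_arms$arm[match(bpp_pairs$marker_2, marker_arms$marker)]
  if (anyNA(a1) || anyNA(a2))
    stopf("every BPP paralog marker must have an arm assignment")
  same <- a1 == a2
  anomalous <- bpp_pairs$pair_id[same]
  lo <- pmin(a1[!same], a2[!same])
  hi <- pmax(a1[!same], a2[!same])
  if (!length(lo)) {
    attr(empty, "anomalous") <- anomalous
    return(empty)
  }
  tab <- table(paste(lo, hi, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  calls <- data.frame(arm_a = vapply(parts, `[`, "", 1),
                      arm_b = vapply(parts, `[`, "", 2),
                      support = as.integer(tab))
  calls <- calls[calls$support >= min_support, , drop = FALSE]
  calls <- calls[order(-calls$support, calls$arm_a, calls$arm_b), ]
  rownames(calls) <- NULL
  attr(calls, "anomalous") <- anomalous
  calls
}

#' Per-arm counts of duplicated and non-duplicated mapped markers
#'
#' @param map map data.frame with \code{marker}, \code{arm} (NA allowed:
#'   grouped under \code{"unassigned"}) and \code{marker_type} in
#'   \code{unique}, \code{OPP}, \code{BPP}.
#' @param top_k also report the fraction of all duplicated loci captured by
#'   the k arms with most duplicates (default 16, the number of arms
#'   carrying most duplicated loci after whole genome duplication).
#' @return list with \code{arms} (per-arm data.frame: \code{n_unique},
#'   \code{n_OPP}, \code{n_BPP}, \code{dup_fraction}) and
#'   \code{top_k_share}.
#' @export
arm_duplicate_summary <- function(map, top_k = 16L) {
  arm <- ifelse(is.na(map$arm), "unassigned", map$arm)
  tab <- table(arm, factor(map$marker_type, levels = c("unique", "OPP", "BPP")))
  arms <- data.frame(arm = rownames(tab),
                     n_unique = as.integer(tab[, "unique"]),
                     n_OPP = as.integer(tab[, "OPP"]),
                     n_BPP = as.integer(tab[, "BPP"]))
  arms$n_dup <- arms$n_OPP + arms$n_BPP
  total <- arms$n_unique + arms$n_dup
  arms$dup_fraction <- ifelse(total > 0, arms$n_dup / total, 0)
  arms <- arms[order(-arms$n_dup, arms$arm), ]
  rownames(arms) <- NULL
  total_dup <- sum(arms$n_dup)
  top_share <- if (total_dup > 0)
    sum(arms$n_dup[seq_len(min(top_k, nrow(arms)))]) / total_dup else NA_real_
  list(arms = arms, top_k_share = top_share)
}

#' Align two reference databases of equal-length loci
#'
#' Cross-species (or cross-study) locus homology: a pair is retained when
#' each locus is the other's only match within \code{max_mismatch}
#' (reciprocal uniqueness); loci matching several partners are dropped.
#'
#' @param db_a,db_b refdb data.frames (\code{locus_id}, \code{sequence});
#'   excluded loci are ignored if a \code{status} column is present.
#' @param max_mismatch maximum mismatches per locus (default 3).
#' @return data.frame \code{locus_a}, \code{locus_b}, \code{mismatches}.
#' @export
crossdb_align <- function(db_a, db_b, max_mismatch = 3L) {
  a <- if ("status" %in% names(db_a))
    db_a[!startsWith(db_a$status, "excluded"), ] else db_a
  b <- if ("status" %in% names(db_b))
    db_b[!startsWith(db_b$status, "excluded"), ] else db_b
  if (length(unique(nchar(c(a$sequence, b$sequence)))) != 1L)
    stopf("databases must have equal locus length")
  D <- hamming_matrix(a$sequence, b$sequence)
  hits <- D <= max_mismatch
  ua <- rowSums(hits) == 1L
  ub <- colSums(hits) == 1L
  ia <- which(ua)
  ib <- max.col(hits[ia, , drop = FALSE], ties.method = "first")
  keep <- ub[ib]
  out <- data.frame(locus_a = a$locus_id[ia[keep]],
                    locus_b = b$locus_id[ib[keep]],
                    mismatches = D[cbind(ia[keep], ib[keep])])
  rownames(out) <- NULL
  out
}
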