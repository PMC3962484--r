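#' Heterozygote-fraction profile of gynogenetic diploids along a map
#'
#' With the second polar body retained, a gynogenetic diploid is
#' heterozygous at a locus exactly when a crossover fell between the locus
#' and the centromere in the maternal meiosis, so the heterozygote fraction
#' y rises from 0 at the centromere toward the telomeres.  Only loci placed
#' on the map and scored in at least one offspring are profiled; duplicated
#' loci should be excluded upstream (they cannot be reliably genotyped in
#' gynogenetic diploids).
#'
#' @param gyno_calls character matrix individuals x loci of genotype strings
#'   (\code{"a/a"}, \code{"a/b"}, NA).
#' @param map map data.frame (\code{group}, \code{marker}, \code{position}).
#' @return data.frame \code{group}, \code{marker}, \code{position},
#'   \code{y}, \code{n}, ordered by group and position.
#' @export
het_profile <- function(gyno_calls, map) {
  common <- intersect(map$marker, colnames(gyno_calls))
  sub <- map[map$marker %in% common, , drop = FALSE]
  het <- matrix(is_het_geno(gyno_calls[, sub$marker, drop = FALSE]),
                nrow = nrow(gyno_calls))
  scored <- !is.na(gyno_calls[, sub$marker, drop = FALSE])
  n <- colSums(scored)
  y <- ifelse(n > 0, colSums(het & scored) / n, NA_real_)
  out <- data.frame(group = sub$group, marker = sub$marker,
                    position = sub$position, y = y, n = n)
  out <- out[out$n > 0, , drop = FALSE]
  out <- out[order(out$group, out$position, out$marker), ]
  rownames(out) <- NULL
  out
}

#' Locate the centromere of one linkage group from its het profile
#'
#' The centromere lies where the heterozygote fraction is about zero: the
#' interval is the maximal run of consecutive loci with y <= y_floor
#' (default 2/n, tolerating one miscalled offspring).  The chromosome is
#' metacentric when loci with y above the floor flank the interval on both
#' sides, acrocentric otherwise.  Under complete interference the
#' gene-centromere distance of each locus is y/2 x 100 cM.
#'
#' @param profile het profile rows for one group (see [het_profile()]).
#' @param y_floor heterozygote-fraction floor; default 2 / median n.
#' @return list with \code{interval} (cM range), \code{midpoint},
#'   \code{type} (\code{"metacentric"}, \code{"acrocentric"} or
#'   \code{"unknown"}), \code{resolved} flag, and \code{distances}
#'   data.frame (\code{marker}, \code{position}, \code{gc_dist} in cM).
#' @export
locate_centromere <- function(profile, y_floor = NULL) {
  if (nrow(profile) < 3L) stopf("need at least 3 profiled loci")
  if (length(unique(profile$group)) != 1L)
    stopf("profile must cover a single linkage group")
  profile <- profile[order(profile$position, profile$marker), ]
  if (is.null(y_floor)) y_floor <- 2 / stats::median(profile$n)
  low <- profile$y <= y_floor
  distances <- data.frame(marker = profile$marker,
                          position = profile$position,
                          gc_dist = profile$y / 2 * 100)
  if (!any(low) || all(low)) {
    return(list(interval = c(NA_real_, NA_real_), midpoint = NA_real_,
                type = "unknown", resolved = FALSE, y_floor = y_floor,
                distances = distances))
  }
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  low_runs <- which(runs$values)
  # maximal run; ties broken by smaller mean y then first
  pick <- low_runs[order(-runs$lengths[low_runs],
                         vapply(low_runs, function(r)
                           mean(profile$y[starts[r]:ends[r]]), numeric(1)))][1]
  i0 <- starts[pick]; i1 <- ends[pick]
  interval <- c(profile$position[i0], profile$position[i1])
  type <- if (i0 > 1L && i1 < nrow(profile)) "metacentric" else "acrocentric"
  list(interval = interval, midpoint = mean(interval), type = type,
       resolved = TRUE, y_floor = y_floor, distances = distances)
}

#' Maximum proportion of heterozygotes (MPH) per chromosome arm
#'
#' MPH summarizes interference: 0.67 without crossover interference, 1.00
#' under complete interference.  Loci are assigned to the p or q arm by
#' their side of the centromere-interval midpoint.
#'
#' @param profile het profile rows for one group.
#' @param centromere result of [locate_centromere()] for that group.
#' @return data.frame \code{arm} (\code{"p"}, \code{"q"}), \code{mph}
#'   (NA when the arm has no profiled loci), \code{n_loci}.
#' @export
compute_mph <- function(profile, centromere) {
  if (!isTRUE(centromere$resolved)) stopf("centromere not resolved")
  mid <- centromere$midpoint
  arm <- ifelse(profile$position < mid, "p", "q")
  out <- lapply(c("p", "q"), function(a) {
    y <- profile$y[arm == a]
    data.frame(arm = a,
               mph = if (length(y)) max(y) else NA_real_,
               n_loci = length(y))
  })
  do.call(rbind, out)
}

#' Align marker allele codings into maternal coupling phase
#'
#' Allele codes of haploid markers are arbitrary per marker; walking the
#' ordered markers, each marker is flipped when more than half of the
#' jointly scored offspring disagree with the previous (already phased)
#' marker, so that phase switches along an offspring reflect crossovers
#' rather than coding.
#'
#' @param X 0/1 matrix (individuals x ordered markers).
#' @return the matrix with columns consistently phased.
#' @export
phase_markers <- function(X) {
  if (ncol(X) < 2L) return(X)
  for (j in 2:ncol(X)) {
    ok <- !is.na(X[, j - 1]) & !is.na(X[, j])
    if (!any(ok)) next
    if (sum(X[ok, j - 1] != X[ok, j]) > sum(ok) / 2)
      X[, j] <- 1L - X[, j]
  }
  X
}

#' Count crossovers per progeny per chromosome arm in a haploid family
#'
#' A haploid offspring carries a single recombinant chromatid; crossovers on
#' an arm appear as maternal-phase switches along the ordered arm markers.
#' Complete interference predicts at most one switch per arm; progeny-arm
#' observations with two or more switches are double crossovers.
#'
#' @param X 0/1 haploid phase matrix (individuals x markers) from
#'   [binarize_haploid()].
#' @param map map data.frame (\code{group}, \code{marker}, \code{position}).
#' @param centromeres named list (by group) of [locate_centromere()]
#'   results; groups without a resolved centromere are treated as one arm.
#' @return list with \code{counts} (data.frame \code{progeny}, \code{group},
#'   \code{arm}, \code{n_crossovers}), \code{summary} (per arm: progeny with
#'   0, 1, 2+ crossovers) and \code{double_crossover_freq} (overall
#'   proportion of progeny-arm observations with 2+ crossovers).
#' @export
count_crossovers <- function(X, map, centromeres = list()) {
  res <- list()
  for (grp in unique(map$group)) {
    sub <- map[map$group == grp, , drop = FALSE]
    sub <- sub[order(sub$position, sub$marker), ]
    cen <- centromeres[[as.character(grp)]]
    mid <- if (!is.null(cen) && isTRUE(cen$resolved)) cen$midpoint else -Inf
    for (a in c("p", "q")) {
      mk <- if (a == "p") sub$marker[sub$position < mid] else
        sub$marker[sub$position >= mid]
      mk <- intersect(mk, colnames(X))
      if (length(mk) < 2L) next  # crossover count undefined
      ph <- phase_markers(X[, mk, drop = FALSE])
      n_sw <- apply(ph, 1L, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2L) return(NA_integer_)
        sum(diff(v) != 0L)
      })
      res[[length(res) + 1L]] <- data.frame(
        progeny = rownames(X), group = grp, arm = a,
        n_crossovers = as.integer(n_sw))
    }
  }
  counts <- if (length(res)) do.call(rbind, res) else
    data.frame(progeny = character(), group = character(), arm = character(),
               n_crossovers = integer())
  ok <- counts[!is.na(counts$n_crossovers), , drop = FALSE]
  cls <- cut(ok$n_crossovers, c(-0.5, 0.5, 1.5, Inf), labels = c("0", "1", "2+"))
  summary <- as.data.frame.matrix(table(paste(ok$group, ok$arm, sep = ":"), cls))
  list(counts = counts, summary = summary,
       double_crossover_freq = if (nrow(ok)) mean(ok$n_crossovers >= 2L)
       else NA_real_)
}
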