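#' Linkage-analysis parameters
#'
#' Grouping uses a maximum recombination fraction of 0.25 and a LOD
#' threshold starting at 3.0, raised in increments of 1.0 until at least
#' \code{target_groups} linkage groups are found — the escalation used to
#' resolve a karyotype of 34 chromosome pairs.
#'
#' @param max_rf maximum recombination fraction for linkage (0 < rf <= 0.5).
#' @param lod_start starting LOD threshold (> 0).
#' @param lod_increment LOD escalation step.
#' @param target_groups stop escalating once at least this many groups.
#' @param map_function \code{"kosambi"} (default), \code{"haldane"} or
#'   \code{"morgan"}.
#' @param min_joint minimum jointly scored offspring for a pair to be
#'   linkable; sparser pairs get LOD 0.
#' @return an object of class \code{linkage_params}.
#' @export
linkage_params <- function(max_rf = 0.25, lod_start = 3.0,
                           lod_increment = 1.0, target_groups = 34L,
                           map_function = c("kosambi", "haldane", "morgan"),
                           min_joint = 10L) {
  if (max_rf <= 0 || max_rf > 0.5) stopf("max_rf must be in (0, 0.5]")
  if (lod_start <= 0) stopf("lod_start must be positive")
  structure(list(max_rf = max_rf, lod_start = lod_start,
                 lod_increment = lod_increment,
                 target_groups = as.integer(target_groups),
                 map_function = match.arg(map_function),
                 min_joint = as.integer(min_joint)),
            class = "linkage_params")
}

#' Two-point recombination fraction and LOD between two haploid markers
#'
#' Over the jointly scored offspring, with R recombinants out of n given the
#' supplied phase (allele coding), rf = R/n (values above 0.5 are reported
#' as 0.5) and LOD = R log10(2 rf) + (n - R) log10(2 (1 - rf)), with the
#' convention 0 log10(0) = 0.  Swapping the phase of one marker maps rf to
#' 1 - rf before clamping.
#'
#' @param calls_i,calls_j vectors of haploid allele codes (any two-level
#'   coding; NA = unscored).
#' @return named numeric vector \code{rf}, \code{lod}, \code{n}, \code{R}.
#' @export
two_point <- function(calls_i, calls_j) {
  ok <- !is.na(calls_i) & !is.na(calls_j)
  n <- sum(ok)
  if (n < 2L) stopf("fewer than 2 jointly scored offspring")
  ref_i <- min(calls_i[ok])
  ref_j <- min(calls_j[ok])
  R <- sum((calls_i[ok] == ref_i) != (calls_j[ok] == ref_j))
  rf_raw <- R / n
  lod <- lod_score(R, n)
  c(rf = min(rf_raw, 0.5), lod = lod, n = n, R = R)
}

#' @noRd
lod_score <- function(R, n) {
  rf <- R / n
  t1 <- ifelse(R == 0, 0, R * log10(2 * rf))
  t2 <- ifelse(R == n, 0, (n - R) * log10(2 * (1 - rf)))
  t1 + t2
}

#' Recode a haploid genotype-call matrix to 0/1 marker phase codes
#'
#' Haploid calls are hemizygous homozygote strings (\code{"a/a"}); the first
#' allele character codes the maternal chromatid.  Markers are kept when
#' exactly two allele codes segregate; offspring carrying a rarer third code
#' (sequencing artifacts) are set missing at that marker.
#'
#' @param calls character matrix individuals x markers.
#' @return integer 0/1 matrix with the same dimnames.
#' @export
binarize_haploid <- function(calls) {
  al <- substr(calls, 1L, 1L)
  X <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (j in seq_len(ncol(calls))) {
    tab <- sort(table(al[, j]), decreasing = TRUE)
    if (length(tab) < 2L) next
    top2 <- sort(names(tab)[1:2])
    X[, j] <- ifelse(al[, j] == top2[1], 1L,
                     ifelse(al[, j] == top2[2], 0L, NA_integer_))
  }
  X
}

#' All-pairs two-point table for a haploid marker matrix
#'
#' Vectorized over marker pairs via indicator cross-products, using
#' pairwise-complete observations.  rf and LOD are phase-minimized
#' (min(R, n - R)), matching the maximum-over-phase behaviour of two-point
#' grouping: haploid marker phase is arbitrary.
#'
#' @param X 0/1 matrix from [binarize_haploid()] (individuals x markers).
#' @param params a [linkage_params()]; pairs with fewer than
#'   \code{min_joint} joint observations get LOD 0 and rf 0.5.
#' @return list of marker x marker matrices \code{rf}, \code{lod}, \code{n},
#'   \code{R}.
#' @export
two_point_table <- function(X, params = linkage_params()) {
  A <- (!is.na(X)) & X == 1L; storage.mode(A) <- "numeric"
  B <- (!is.na(X)) & X == 0L; storage.mode(B) <- "numeric"
  A[is.na(A)] <- 0; B[is.na(B)] <- 0
  N <- crossprod(A + B)
  same <- crossprod(A) + crossprod(B)
  R <- N - same
  Rm <- pmin(R, N - R)
  rf <- ifelse(N > 0, Rm / N, 0.5)
  lod <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(N))
  ok <- N >= params$min_joint
  lod[ok] <- lod_score(Rm[ok], N[ok])
  rf[!ok] <- 0.5
  lod[!ok] <- 0
  diag(lod) <- 0; diag(rf) <- 0
  list(rf = rf, lod = lod, n = N, R = Rm)
}

#' Partition markers into linkage groups by LOD-escalated single linkage
#'
#' Single-linkage transitive closure over marker pairs with rf <= max_rf and
#' LOD >= threshold; the threshold starts at \code{lod_start} and rises by
#' \code{lod_increment} until the partition has at least
#' \code{target_groups} groups (or no edges remain).
#'
#' @param tp two-point table from [two_point_table()].
#' @param params a [linkage_params()].
#' @return list with \code{groups} (named integer membership, renumbered by
#'   decreasing group size), \code{n_groups}, \code{final_lod}.
#' @export
form_groups <- function(tp, params = linkage_params()) {
  n_mark <- nrow(tp$lod)
  if (n_mark < params$target_groups)
    stopf("fewer markers (%d) than target_groups (%d)", n_mark,
          params$target_groups)
  thr <- params$lod_start
  repeat {
    adj <- tp$rf <= params$max_rf & tp$lod >= thr
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
    comp <- igraph::components(g)
    if (comp$no >= params$target_groups || !any(adj)) break
    thr <- thr + params$lod_increment
  }
  sizes <- comp$csize
  renum <- order(-sizes)
  memb <- match(comp$membership, renum)
  names(memb) <- colnames(tp$lod)
  list(groups = memb, n_groups = comp$no, final_lod = thr)
}

#' Map distance (cM) from a recombination fraction
#'
#' @param rf recombination fraction(s) in [0, 0.5].
#' @param map_function \code{"kosambi"}, \code{"haldane"} or \code{"morgan"}.
#' @return distances in cM (capped at rf = 0.4999 for the log functions).
#' @export
map_distance <- function(rf, map_function = "kosambi") {
  rf <- pmin(rf, 0.4999)
  switch(map_function,
         kosambi = 25 * log((1 + 2 * rf) / (1 - 2 * rf)),
         haldane = -50 * log(1 - 2 * rf),
         morgan = 100 * rf,
         stopf("unknown map function '%s'", map_function))
}

#' Order the markers of one linkage group
#'
#' Co-segregating markers (zero recombinants over joint observations) are
#' first collapsed into bins represented by their lexicographically smallest
#' marker id.  Bins are then ordered to minimize the total adjacent
#' recombinant count (seriation: nearest-neighbour path construction from
#' the most distal bin, improved by 2-opt to convergence).  Adjacent
#' distances come from the selected map function; bin members share their
#' bin's position.  Orientation is standardized so the first marker id is
#' lexicographically smaller than the last (flip later via
#' [anchor_groups()] for p-arm-first orientation).
#'
#' @param markers marker ids of the group.
#' @param X 0/1 haploid matrix (individuals x all markers).
#' @param params a [linkage_params()].
#' @return data.frame \code{marker}, \code{bin}, \code{position} (cM,
#'   nondecreasing).
#' @export
order_markers <- function(markers, X, params = linkage_params()) {
  if (length(markers) == 1L)
    return(data.frame(marker = markers, bin = markers, position = 0))
  tp <- two_point_table(X[, markers, drop = FALSE], params)
  # bin co-segregating markers
  cosegr <- tp$R == 0 & tp$n >= params$min_joint
  diag(cosegr) <- TRUE
  gb <- igraph::components(igraph::graph_from_adjacency_matrix(cosegr,
                                                               mode = "max"))
  bin_of <- gb$membership
  reps <- vapply(seq_len(gb$no), function(b) min(markers[bin_of == b]),
                 character(1))
  k <- length(reps)
  if (k == 1L)
    return(data.frame(marker = markers, bin = reps[bin_of],
                      position = rep(0, length(markers))))
  ri <- match(reps, markers)
  Rb <- tp$R[ri, ri, drop = FALSE]
  Nb <- tp$n[ri, ri, drop = FALSE]
  ord <- seriate_path(Rb)
  # standardize orientation by marker id
  if (reps[ord[1]] > reps[ord[k]]) ord <- rev(ord)
  rf_adj <- vapply(seq_len(k - 1), function(i) {
    n <- Nb[ord[i], ord[i + 1]]
    if (n > 0) Rb[ord[i], ord[i + 1]] / n else 0
  }, numeric(1))
  pos_bin <- c(0, cumsum(map_distance(rf_adj, params$map_function)))
  names(pos_bin) <- reps[ord]
  out <- data.frame(marker = markers, bin = reps[bin_of],
                    position = pos_bin[reps[bin_of]])
  out <- out[order(out$position, out$marker), ]
  rownames(out) <- NULL
  out
}

#' Total adjacent recombinant count of an order (seriation objective)
#' @noRd
order_objective <- function(ord, R) {
  sum(R[cbind(ord[-length(ord)], ord[-1])])
}

#' Nearest-neighbour path + 2-opt seriation on a recombinant-count matrix
#' @noRd
seriate_path <- function(R) {
  k <- nrow(R)
  if (k <= 2L) return(seq_len(k))
  nn_from <- function(start) {
    ord <- integer(k); used <- logical(k)
    ord[1] <- start; used[start] <- TRUE
    for (i in 2:k) {
      cand <- which(!used)
      nxt <- cand[which.min(R[ord[i - 1], cand])]
      ord[i] <- nxt; used[nxt] <- TRUE
    }
    ord
  }
  # multi-start nearest neighbour (all starts when the group is small)
  starts <- if (k <= 30L) seq_len(k) else
    unique(c(which.max(rowSums(R)), 1L, k))
  cands <- lapply(starts, nn_from)
  objs <- vapply(cands, order_objective, numeric(1), R = R)
  ord <- cands[[which.min(objs)]]
  best <- min(objs)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        cand <- c(if (i > 1) ord[seq_len(i - 1)], rev(ord[i:j]),
                  if (j < k) ord[seq(j + 1, k)])
        val <- order_objective(cand, R)
        if (val < best) {
          ord <- cand; best <- val; improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Merge per-family maps into a consensus map
#'
#' Family maps of one linkage group are matched when they share at least two
#' markers, and their orientations are aligned by rank correlation of shared
#' markers.  A directed precedence graph collects every within-family order
#' relation; if it is acyclic the consensus order is a topological order,
#' with family-unique markers carried by their own family's relations and
#' positions interpolated from rescaled per-family positions.  Cyclic
#' conflicts are resolved by dropping, from each strongly connected
#' component, the marker seen in fewest families (ties: lexicographically
#' largest dropped first); dropped markers go to the conflict report.
#'
#' @param family_maps named list of map data.frames (\code{group},
#'   \code{marker}, \code{position}).
#' @return list with \code{map} (consensus data.frame \code{group},
#'   \code{marker}, \code{position}), \code{conflicts} (data.frame
#'   \code{marker}, \code{reason}) and \code{unmerged} (family-specific
#'   groups kept as is, with a warning already issued).
#' @export
merge_maps <- function(family_maps) {
  if (length(family_maps) < 2L) stopf("need at least 2 family maps")
  units <- list()
  for (fam in names(family_maps)) {
    m <- family_maps[[fam]]
    for (grp in unique(m$group)) {
      sub <- m[m$group == grp, ]
      sub <- sub[order(sub$position, sub$marker), ]
      units[[paste(fam, grp, sep = ":")]] <-
        list(family = fam, group = grp, markers = sub$marker,
             positions = sub$position)
    }
  }
  # match units across families by shared markers (>= 2)
  nu <- length(units)
  adj <- matrix(FALSE, nu, nu)
  for (i in seq_len(nu)) for (j in seq_len(nu)) {
    if (i < j && units[[i]]$family != units[[j]]$family)
      adj[i, j] <- adj[j, i] <-
        length(intersect(units[[i]]$markers, units[[j]]$markers)) >= 2L
  }
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj,
                                                                 mode = "max"))
  out <- list(); conflicts <- list(); unmerged <- list()
  for (cc in seq_len(comp$no)) {
    members <- units[comp$membership == cc]
    if (length(members) == 1L) {
      u <- members[[1]]
      warning(sprintf("group %s of family %s shares no markers; kept family-specific",
                      u$group, u$family))
      unmerged[[length(unmerged) + 1L]] <-
        data.frame(group = paste0("U", cc), marker = u$markers,
                   position = u$positions)
      next
    }
    merged <- merge_unit_set(members)
    out[[length(out) + 1L]] <-
      data.frame(group = paste0("G", length(out) + 1L),
                 marker = merged$marker, position = merged$position)
    if (nrow(merged$conflicts))
      conflicts[[length(conflicts) + 1L]] <- merged$conflicts
  }
  list(map = if (length(out)) do.call(rbind, out) else NULL,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(marker = character(), reason = character()),
       unmerged = if (length(unmerged)) do.call(rbind, unmerged) else NULL)
}

#' @noRd
merge_unit_set <- function(members) {
  # orient every unit to agree with the first
  ref <- members[[1]]
  for (i in seq_along(members)[-1]) {
    u <- members[[i]]
    shared <- intersect(ref$markers, u$markers)
    if (length(shared) >= 2L) {
      r1 <- match(shared, ref$markers)
      r2 <- match(shared, u$markers)
      if (cor(r1, r2, method = "kendall") < 0) {
        members[[i]]$markers <- rev(u$markers)
        members[[i]]$positions <- rev(max(u$positions) - u$positions)
      }
    }
  }
  all_markers <- sort(unique(unlist(lapply(members, `[[`, "markers"))))
  fam_count <- table(unlist(lapply(members, function(u) unique(u$markers))))
  dropped <- character()
  repeat {
    edges <- do.call(rbind, lapply(members, function(u) {
      mk <- setdiff(u$markers, dropped)
      if (length(mk) < 2L) return(NULL)
      t(combn(seq_along(mk), 2, function(ix) c(mk[ix[1]], mk[ix[2]])))
    }))
    keep_markers <- setdiff(all_markers, dropped)
    g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                       vertices = keep_markers)
    scc <- igraph::components(g, mode = "strong")
    if (max(scc$csize) == 1L) break
    bad_comp <- which(scc$csize > 1L)
    for (b in bad_comp) {
      mk <- names(scc$membership)[scc$membership == b]
      support <- as.numeric(fam_count[mk])
      victim <- mk[order(support, -rank(mk))][1]  # fewest families, lex largest
      dropped <- c(dropped, victim)
    }
  }
  topo <- names(igraph::topo_sort(g, mode = "out"))
  # consensus positions: mean of per-family rescaled positions
  span <- vapply(members, function(u) max(u$positions), numeric(1))
  mean_len <- mean(span[span > 0])
  if (!is.finite(mean_len)) mean_len <- 0
  relpos <- lapply(members, function(u) {
    s <- max(u$positions)
    stats::setNames(if (s > 0) u$positions / s else rep(0, length(u$positions)),
                    u$markers)
  })
  pos <- vapply(topo, function(mk) {
    v <- unlist(lapply(relpos, function(rp) rp[mk]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  pos <- cummax(pos) * mean_len
  list(marker = topo, position = unname(pos),
       conflicts = if (length(dropped))
       data.frame(marker = dropped, reason = "order conflict between families")
       else data.frame(marker = character(), reason = character()))
}

#' Anchor linkage groups to chromosomes and standardize orientation
#'
#' Each group is labelled by majority vote of its anchor markers (markers of
#' known chromosome, e.g. previously mapped microsatellites); conflicting
#' anchors are reported.  Where anchors carry arm labels, the group is
#' oriented p-arm first: if the mean position of p-arm anchors exceeds that
#' of q-arm anchors the group is flipped.
#'
#' @param map map data.frame (\code{group}, \code{marker}, \code{position}).
#' @param anchors data.frame (\code{marker}, \code{chrom}, optional
#'   \code{arm}).
#' @return list with \code{map} (adds \code{chrom}; positions possibly
#'   flipped) and \code{conflicts} data.frame.
#' @export
anchor_groups <- function(map, anchors) {
  map$chrom <- NA
  conflicts <- list()
  for (grp in unique(map$group)) {
    idx <- map$group == grp
    a <- anchors[anchors$marker %in% map$marker[idx], , drop = FALSE]
    if (!nrow(a)) next
    votes <- sort(table(a$chrom), decreasing = TRUE)
    map$chrom[idx] <- names(votes)[1]
    if (length(votes) > 1L)
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(group = grp, chrom = names(votes)[-1],
                   n_anchors = as.integer(votes[-1]))
    if ("arm" %in% names(a) && any(a$arm == "p", na.rm = TRUE) &&
        any(a$arm == "q", na.rm = TRUE)) {
      posn <- map$position[idx][match(a$marker, map$marker[idx])]
      if (mean(posn[a$arm == "p"], na.rm = TRUE) >
          mean(posn[a$arm == "q"], na.rm = TRUE)) {
        map$position[idx] <- max(map$position[idx]) - map$position[idx]
        sub <- map[idx, ]
        sub <- sub[order(sub$position, sub$marker), ]
        map[idx, ] <- sub
      }
    }
  }
  list(map = map,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(group = character(), chrom = character(),
                    n_anchors = integer()))
}
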