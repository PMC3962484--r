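#' Built-in simulation configurations
#'
#' \code{tiny} is a seconds-scale fixture (2 chromosomes, 1 homeolog pair,
#' small families) for unit tests; \code{demo} is the full 34-chromosome
#' karyotype with the study-scale family structure: three haploid families
#' of 46, 48 and 72 offspring, three gynogenetic diploid families of 84, 90
#' and 93 progeny, and a locus-discovery panel of unrelated diploids.
#'
#' @param scale \code{"tiny"} or \code{"demo"}.
#' @return a configuration list consumable by [run_pipeline()].
#' @export
make_fixtures <- function(scale = c("tiny", "demo")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    list(
      genome = list(
        karyotype = list(n_metacentric = 1L, n_acrocentric = 1L,
                         p_met = 50, q_met = 60, q_acro = 80, p_acro = 0),
        loci_per_chrom = 18L,
        homeolog_pairs = list(list(pair_id = "H1", chrom_a = 1L, arm_a = "q",
                                   chrom_b = 2L, arm_b = "q",
                                   divergence = 2L)),
        dup_per_pair = 4L),
      crosses = list(
        haploid = list(A = 24L),
        gynogenetic_diploid = list(G1 = 24L)),
      panel = list(n_individuals = 24L),
      reads = list(mean_depth = 30, depth_dispersion = 10,
                   error_rate = 0, error_mode = "novel"),
      interference = "complete",
      linkage = list(target_groups = 2L, lod_start = 3.0)
    )
  } else {
    list(
      genome = list(
        karyotype = list(n_metacentric = 16L, n_acrocentric = 18L,
                         p_met = 50, q_met = 60, q_acro = 80, p_acro = 0),
        loci_per_chrom = 10L,
        homeolog_pairs = lapply(1:8, function(i)
          list(pair_id = sprintf("H%d", i),
               chrom_a = i, arm_a = "q",
               chrom_b = 16L + i, arm_b = "q",
               divergence = ((i - 1L) %% 3L) + 1L)),
        dup_per_pair = 4L),
      crosses = list(
        haploid = list(A = 46L, B = 48L, C = 72L),
        gynogenetic_diploid = list(G1 = 84L, G2 = 90L, G3 = 93L)),
      panel = list(n_individuals = 60L),
      reads = list(mean_depth = 20, depth_dispersion = 10,
                   error_rate = 0.002, error_mode = "novel"),
      interference = "complete",
      linkage = list(target_groups = 34L, lod_start = 3.0)
    )
  }
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with \code{genome}, \code{crosses}, \code{panel},
#'   \code{reads}, \code{interference} and \code{linkage} sections (see
#'   [make_fixtures()] for the shape).
#' @return configuration list.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  for (section in c("genome", "crosses")) {
    if (is.null(cfg[[section]]))
      stopf("config is missing the '%s' section", section)
  }
  if (is.null(cfg$genome$karyotype)) stopf("config genome needs a karyotype")
  invisible(cfg)
}

#' Build a genome from a configuration list
#'
#' @param cfg configuration list (see [make_fixtures()]).
#' @param seed RNG seed for locus placement and sequence generation.
#' @return a [build_genome()] result.
#' @export
genome_from_config <- function(cfg, seed = 1L) {
  ka <- do.call(chinook_karyotype, cfg$genome$karyotype)
  hp <- NULL
  if (length(cfg$genome$homeolog_pairs))
    hp <- do.call(rbind, lapply(cfg$genome$homeolog_pairs, as.data.frame))
  loci <- place_loci(genome_config(ka)$chromosomes, hp,
                     n_per_chrom = cfg$genome$loci_per_chrom %||% 10L,
                     n_dup_per_pair = cfg$genome$dup_per_pair %||% 0L,
                     seed = derive_seed(seed, "place"))
  build_genome(genome_config(ka, hp, loci, seed = derive_seed(seed, "genome")))
}

#' Run the full pipeline: simulate, build database, genotype, map,
#' locate centromeres, characterize duplications
#'
#' Stages run in a fixed order; each writes its outputs under
#' \code{out_dir} before the next starts, and a manifest records paths,
#' stage status, the configuration digest and the seed.  Identical config
#' and seed give byte-identical outputs.
#'
#' @param cfg configuration list ([make_fixtures()] or [read_sim_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed global seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @return the run manifest (list), invisibly; all tables are also returned
#'   in the \code{results} element.
#' @export
run_pipeline <- function(cfg, out_dir, seed = 1L) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed,
                   config_digest = config_digest(cfg),
                   tool_version = as.character(utils::packageVersion("salhap")),
                   stages = list())
  record <- function(stage, paths) {
    manifest$stages[[stage]] <<- list(status = "ok", outputs = paths)
  }
  fail <- function(stage, e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }

  ## stage 1: simulate
  res <- tryCatch({
    genome <- genome_from_config(cfg, seed)
    truth_loci <- genome$loci[, c("locus_id", "chrom", "pos", "is_duplicated",
                                  "pair_id", "dup_class", "dam_1", "dam_2")]
    fa <- file.path(out_dir, "true_loci.fasta")
    seqs <- Biostrings::DNAStringSet(genome$loci$sequence)
    names(seqs) <- genome$loci$locus_id
    Biostrings::writeXStringSet(seqs, fa)
    write_tsv(truth_loci, file.path(out_dir, "truth_loci.tsv"))
    write_tsv(genome$chromosomes, file.path(out_dir, "truth_chromosomes.tsv"))
    if (!is.null(genome$homeolog_pairs))
      write_tsv(genome$homeolog_pairs, file.path(out_dir, "truth_homeologs.tsv"))
    rd <- cfg$reads %||% list()
    crosses <- list(); pileups <- list()
    i <- 0L
    for (ct in names(cfg$crosses)) {
      for (fam in names(cfg$crosses[[ct]])) {
        i <- i + 1L
        spec <- cross_spec(ct, cfg$crosses[[ct]][[fam]],
                           interference = cfg$interference %||% "complete",
                           family_id = fam)
        cr <- simulate_cross(genome, spec, seed = derive_seed(seed, 100L + i))
        crosses[[fam]] <- cr
        pileups[[fam]] <- simulate_reads(
          genome, cr$genotypes,
          mean_depth = rd$mean_depth %||% 30,
          depth_dispersion = rd$depth_dispersion %||% 10,
          error_rate = rd$error_rate %||% 0,
          error_mode = rd$error_mode %||% "novel",
          seed = derive_seed(seed, 200L + i))
        write_tsv(pileups[[fam]], file.path(out_dir,
                                            sprintf("pileup_%s.tsv", fam)))
        write_genotype_tsv(cr$genotypes,
                           file.path(out_dir, sprintf("truth_geno_%s.tsv", fam)))
      }
    }
    panel_geno <- NULL; panel_pileup <- NULL
    if (!is.null(cfg$panel)) {
      panel_geno <- simulate_panel(genome, cfg$panel$n_individuals,
                                   seed = derive_seed(seed, "panel"))
      panel_pileup <- simulate_reads(
        genome, panel_geno,
        mean_depth = rd$mean_depth %||% 30,
        depth_dispersion = rd$depth_dispersion %||% 10,
        error_rate = rd$error_rate %||% 0,
        error_mode = rd$error_mode %||% "novel",
        seed = derive_seed(seed, "panelreads"))
      write_tsv(panel_pileup, file.path(out_dir, "pileup_panel.tsv"))
    }
    list(genome = genome, crosses = crosses, pileups = pileups,
         panel_pileup = panel_pileup)
  }, error = function(e) fail("simulate", e))
  record("simulate", list.files(out_dir, "^(true|truth|pileup)"))

  ## stage 2: reference database
  params <- screening_params()
  hap_fams <- names(cfg$crosses$haploid)
  refdb <- tryCatch({
    panel_pp <- res$panel_pileup %||% do.call(rbind, res$pileups[hap_fams])
    rdb <- build_refdb(panel_pp, res$pileups[hap_fams],
                       n_individuals = length(unique(panel_pp$individual_id)),
                       params = params)
    write_refdb_fasta(rdb$db, file.path(out_dir, "refdb.fasta"))
    rdb
  }, error = function(e) fail("build-refdb", e))
  record("build-refdb", c("refdb.fasta", "refdb.tsv"))

  ## stage 3: genotyping of all crosses against the database
  calls <- tryCatch({
    out <- lapply(names(res$pileups), function(fam) {
      assigned <- align_to_db(res$pileups[[fam]], refdb$db, params)
      m <- call_genotype_matrix(assigned, params)
      write_genotype_tsv(m, file.path(out_dir, sprintf("calls_%s.tsv", fam)))
      m
    })
    names(out) <- names(res$pileups)
    out
  }, error = function(e) fail("genotype", e))
  record("genotype", sprintf("calls_%s.tsv", names(res$pileups)))

  ## stage 4: per-family linkage maps and consensus
  lp <- linkage_params(
    target_groups = cfg$linkage$target_groups %||% 34L,
    lod_start = cfg$linkage$lod_start %||% 3.0)
  mapping <- tryCatch({
    fam_maps <- list(); fam_X <- list(); marker_class <- list()
    for (fam in hap_fams) {
      hm <- haploid_marker_matrix(calls[[fam]], refdb$db)
      fam_X[[fam]] <- hm$X
      marker_class[[fam]] <- hm$marker_type
      tp <- two_point_table(hm$X, lp)
      grp <- form_groups(tp, lp)
      ords <- lapply(sort(unique(grp$groups)), function(g) {
        mk <- names(grp$groups)[grp$groups == g]
        o <- order_markers(mk, hm$X, lp)
        o$group <- sprintf("LG%02d", g)
        o
      })
      fam_maps[[fam]] <- do.call(rbind, ords)
      write_tsv(fam_maps[[fam]],
                file.path(out_dir, sprintf("map_%s.tsv", fam)))
    }
    cons <- if (length(fam_maps) >= 2L) merge_maps(fam_maps) else
      list(map = fam_maps[[1]], conflicts = NULL, unmerged = NULL)
    anchors <- truth_anchors(res$genome, refdb$db)
    anchored <- anchor_groups(cons$map, anchors)
    write_tsv(anchored$map, file.path(out_dir, "map_consensus.tsv"))
    list(fam_maps = fam_maps, fam_X = fam_X, marker_class = marker_class,
         consensus = anchored$map, conflicts = cons$conflicts,
         anchors = anchors)
  }, error = function(e) fail("map", e))
  record("map", c(sprintf("map_%s.tsv", hap_fams), "map_consensus.tsv"))

  ## stage 5: centromeres, MPH, crossovers
  centro <- tryCatch({
    gyno_fams <- names(cfg$crosses$gynogenetic_diploid)
    gyno_calls <- do.call(rbind, calls[gyno_fams])
    dup_ids <- refdb$db$locus_id[refdb$db$status == "duplicated"]
    gyno_calls <- gyno_calls[, setdiff(colnames(gyno_calls), dup_ids),
                             drop = FALSE]
    # first pass: locate centromeres, then standardize orientation so the
    # shorter (p) side precedes the centromere, and re-profile
    prof <- het_profile(gyno_calls, mapping$consensus)
    for (grp in unique(prof$group)) {
      p <- prof[prof$group == grp, ]
      if (nrow(p) < 3L) next
      cen <- locate_centromere(p)
      idx <- mapping$consensus$group == grp
      span <- max(mapping$consensus$position[idx])
      if (cen$resolved && cen$midpoint > span - cen$midpoint) {
        mapping$consensus$position[idx] <- span -
          mapping$consensus$position[idx]
        sub <- mapping$consensus[idx, ]
        sub <- sub[order(sub$position, sub$marker), ]
        mapping$consensus[idx, ] <- sub
      }
    }
    prof <- het_profile(gyno_calls, mapping$consensus)
    write_tsv(mapping$consensus, file.path(out_dir, "map_consensus.tsv"))
    cents <- list(); mph <- list()
    for (grp in unique(prof$group)) {
      p <- prof[prof$group == grp, ]
      if (nrow(p) < 3L) next
      cen <- locate_centromere(p)
      cents[[as.character(grp)]] <- cen
      if (cen$resolved) {
        m <- compute_mph(p, cen)
        m$group <- grp
        mph[[as.character(grp)]] <- m
      }
    }
    cen_tab <- do.call(rbind, lapply(names(cents), function(g)
      data.frame(group = g, interval_lo = cents[[g]]$interval[1],
                 interval_hi = cents[[g]]$interval[2],
                 type = cents[[g]]$type)))
    write_tsv(prof, file.path(out_dir, "het_profile.tsv"))
    if (!is.null(cen_tab)) write_tsv(cen_tab, file.path(out_dir, "centromeres.tsv"))
    if (length(mph)) write_tsv(do.call(rbind, mph), file.path(out_dir, "mph.tsv"))
    xo <- count_crossovers(mapping$fam_X[[hap_fams[1]]], mapping$consensus,
                           cents)
    write_tsv(xo$counts, file.path(out_dir, "crossovers.tsv"))
    list(profile = prof, centromeres = cents, mph = mph, crossovers = xo)
  }, error = function(e) fail("centromere", e))
  record("centromere", c("het_profile.tsv", "centromeres.tsv", "mph.tsv",
                         "crossovers.tsv"))

  ## stage 6: duplication analysis
  dup <- tryCatch({
    cmap <- mapping$consensus
    mtypes <- do.call(rbind, mapping$marker_class)
    mtypes <- mtypes[!duplicated(mtypes$marker), ]
    cmap$marker_type <- mtypes$type[match(cmap$marker, mtypes$marker)]
    cmap$marker_type[is.na(cmap$marker_type)] <- "unique"
    cmap$is_duplicated <- cmap$marker_type != "unique"
    dens <- duplicate_density(cmap)
    write_tsv(dens, file.path(out_dir, "duplicate_density.tsv"))
    cmap$arm <- marker_arm(cmap, centro$centromeres)
    summ <- arm_duplicate_summary(cmap)
    write_tsv(summ$arms, file.path(out_dir, "arm_summary.tsv"))
    bpp <- mtypes[mtypes$type == "BPP", ]
    hom <- NULL
    if (nrow(bpp)) {
      roots <- unique(bpp$root)
      pairs <- data.frame(pair_id = roots,
                          marker_1 = paste0(roots, "_p1"),
                          marker_2 = paste0(roots, "_p2"))
      # both paralogs must be mapped on a group with a located centromere
      arm_of <- stats::setNames(cmap$arm, cmap$marker)
      pairs <- pairs[pairs$marker_1 %in% cmap$marker &
                       pairs$marker_2 %in% cmap$marker, ]
      pairs <- pairs[!is.na(arm_of[pairs$marker_1]) &
                       !is.na(arm_of[pairs$marker_2]), , drop = FALSE]
      if (nrow(pairs)) {
        hom <- infer_homeologies(pairs,
                                 data.frame(marker = cmap$marker,
                                            arm = cmap$arm))
        write_tsv(hom, file.path(out_dir, "homeologies.tsv"))
      }
    }
    list(density = dens, arm_summary = summ, homeologies = hom)
  }, error = function(e) fail("duplication", e))
  record("duplication", c("duplicate_density.tsv", "arm_summary.tsv",
                          "homeologies.tsv"))

  manifest$results <- list(genome = res$genome, refdb = refdb$db,
                           calls = calls, map = mapping$consensus,
                           family_maps = mapping$fam_maps,
                           centromere = centro, duplication = dup)
  yaml::write_yaml(manifest[c("seed", "config_digest", "tool_version")],
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' @noRd
config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Build the haploid marker matrix for mapping: unique loci plus
#' decomposed duplicated markers
#'
#' Unique loci contribute their hemizygous phase codes directly; duplicated
#' loci are classified from their composite segregation
#' ([infer_duplicate_marker()]) and contribute one (OPP) or two (BPP)
#' decomposed paralog markers named \code{<locus>_p1} / \code{<locus>_p2}.
#'
#' @param calls haploid call matrix from [call_genotype_matrix()].
#' @param db refdb data.frame with duplicate status.
#' @return list with \code{X} (0/1 matrix) and \code{marker_type}
#'   (data.frame \code{marker}, \code{root}, \code{type}).
#' @export
haploid_marker_matrix <- function(calls, db) {
  dup_ids <- intersect(colnames(calls),
                       db$locus_id[db$status == "duplicated"])
  uniq_ids <- intersect(colnames(calls),
                        db$locus_id[db$status == "unique"])
  X <- binarize_haploid(calls[, uniq_ids, drop = FALSE])
  mtype <- data.frame(marker = uniq_ids, root = uniq_ids, type = "unique")
  for (lid in dup_ids) {
    inf <- infer_duplicate_marker(stats::setNames(calls[, lid],
                                                  rownames(calls)))
    if (is.null(inf$decomposed)) next
    d <- inf$decomposed
    cols <- paste0(lid, "_", colnames(d))
    keep <- if (startsWith(inf$class, "OPP")) cols[1] else cols
    Xd <- binarize_haploid(matrix(paste0(d, "/", d), nrow = nrow(d),
                                  dimnames = list(rownames(calls), cols)))
    X <- cbind(X, Xd[, seq_along(keep), drop = FALSE])
    colnames(X)[(ncol(X) - length(keep) + 1L):ncol(X)] <- keep
    mtype <- rbind(mtype, data.frame(marker = keep, root = lid,
                                     type = substr(inf$class, 1, 3)))
  }
  list(X = X, marker_type = mtype)
}

#' Arm label of each mapped marker from located centromeres
#' @noRd
marker_arm <- function(map, centromeres) {
  arm <- rep(NA_character_, nrow(map))
  for (grp in unique(map$group)) {
    idx <- map$group == grp
    cen <- centromeres[[as.character(grp)]]
    if (is.null(cen) || !isTRUE(cen$resolved)) next
    side <- ifelse(map$position[idx] < cen$midpoint, "p", "q")
    lab <- if (!is.na(map$chrom[idx][1])) map$chrom[idx][1] else grp
    arm[idx] <- paste0(lab, side)
  }
  arm
}

#' Anchor table from simulation truth (stands in for previously mapped
#' microsatellite markers)
#'
#' Matches database consensi back to the true loci by unique k-mismatch
#' alignment and picks up to three non-duplicated anchors per chromosome,
#' spread along it, labelled with the true chromosome and arm.
#'
#' @param genome a [build_genome()] result.
#' @param db refdb data.frame.
#' @param per_chrom anchors per chromosome.
#' @return data.frame \code{marker}, \code{chrom}, \code{arm}.
#' @export
truth_anchors <- function(genome, db, per_chrom = 3L) {
  uniq <- db[db$status == "unique", , drop = FALSE]
  truth <- genome$loci[!genome$loci$is_duplicated, , drop = FALSE]
  if (!nrow(uniq) || !nrow(truth))
    return(data.frame(marker = character(), chrom = character(),
                      arm = character()))
  D <- hamming_matrix(uniq$sequence, truth$sequence)
  hits <- D <= 3L
  one <- rowSums(hits) == 1L
  match_idx <- max.col(hits, ties.method = "first")
  anchors <- data.frame(marker = uniq$locus_id[one],
                        chrom = truth$chrom[match_idx[one]],
                        pos = truth$pos[match_idx[one]])
  cenpos <- genome$chromosomes$centromere[
    match(anchors$chrom, genome$chromosomes$chrom)]
  anchors$arm <- ifelse(anchors$pos <= cenpos, "p", "q")
  out <- do.call(rbind, lapply(split(anchors, anchors$chrom), function(a) {
    a <- a[order(a$pos), ]
    a[unique(round(seq(1, nrow(a), length.out = min(per_chrom, nrow(a))))), ]
  }))
  rownames(out) <- NULL
  out[, c("marker", "chrom", "arm")]
}
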