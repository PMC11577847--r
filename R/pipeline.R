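#' Full linkage-mapping pipeline for a full-sib cross
#'
#' Runs the complete workflow on a genotype matrix: marker QC
#' ([qc_markers()]), per-parent transmissions, all-pairs two-point LOD,
#' linkage-group formation at `lod_threshold` with rescue of unassigned
#' markers, per-group marker ordering (Kosambi, identical-limit binning,
#' physical seeding), sex-specific map estimation, orientation along the
#' physical map, edge trimming with a second ordering pass, and per-group /
#' genome-wide summaries.
#'
#' @param gm A [genotype_matrix()] with genotyped parents.
#' @param lod_threshold LOD threshold for grouping (11 for one large family,
#'   5 for multi-family data).
#' @param min_size Minimal linkage-group size (default 5).
#' @param mask Informativeness mask (default `c(1, 2, 3)`; use `c(1, 2)` for
#'   multi-family data).
#' @param alpha,max_missing QC thresholds, see [qc_markers()].
#' @param rescue_lod,rescue_diff Rescue thresholds, see
#'   [rescue_unassigned()].
#' @param identical_limit,use_physical Ordering parameters, see
#'   [order_markers()].
#' @param trim Apply [trim_edges()] plus a re-ordering pass (default `TRUE`).
#' @param edge_fraction,gap_fraction Trimming parameters.
#' @param chrom_lengths Optional data.frame (`chromosome`, `length_bp`) used
#'   for per-chromosome physical lengths; otherwise the marker bp span of
#'   each group is used.
#' @param assembly_length_mb Optional assembly length for genome-wide rates.
#' @param seed Seed for the ordering search.
#' @return List with `qc` (QC report), `groups`, `unassigned`, `maps` (named
#'   list of `sex_map`), `summaries` (per-group [chromosome_summary()] rows)
#'   and `genome` (a [genome_summary()]).
#' @export
linkage_pipeline <- function(gm, lod_threshold = 11, min_size = 5,
                             mask = c(1, 2, 3), alpha = 1e-4,
                             max_missing = 0.25,
                             rescue_lod = 2, rescue_diff = 2,
                             identical_limit = 0.005, use_physical = TRUE,
                             trim = TRUE, edge_fraction = 0.10,
                             gap_fraction = 0.05,
                             chrom_lengths = NULL, assembly_length_mb = NULL,
                             seed = 42L) {
  qc <- qc_markers(gm, mask = mask, alpha = alpha, max_missing = max_missing)
  tr <- marker_transmissions(qc$geno)
  pairs <- pairwise_lod_matrix(tr)
  grp <- group_markers(pairs$lod, lod_threshold, min_size)
  grp <- rescue_unassigned(grp$groups, grp$unassigned, pairs$lod,
                           rescue_lod, rescue_diff)

  mk <- qc$geno$markers
  build_map <- function(members) {
    sub <- mk[mk$marker %in% members, , drop = FALSE]
    ord <- order_markers(sub, pairs, identical_limit = identical_limit,
                         use_physical = use_physical, seed = seed)
    map <- orient_map(estimate_map_positions(ord$order, tr))
    if (trim && nrow(map) >= 10) {
      tm <- trim_edges(map, edge_fraction, gap_fraction)
      if (length(tm$removed)) {
        sub2 <- sub[!sub$marker %in% tm$removed, , drop = FALSE]
        ord2 <- order_markers(sub2, pairs, identical_limit = identical_limit,
                              use_physical = use_physical, seed = seed)
        map <- orient_map(estimate_map_positions(ord2$order, tr))
      }
    }
    map
  }
  maps <- lapply(grp$groups, build_map)

  len_of <- function(map) {
    chrom <- names(sort(-table(map$chrom)))[1]
    if (!is.null(chrom_lengths) &&
        chrom %in% chrom_lengths$chromosome) {
      chrom_lengths$length_bp[match(chrom, chrom_lengths$chromosome)] / 1e6
    } else {
      max(map$pos) / 1e6
    }
  }
  summaries <- do.call(rbind, lapply(maps, function(m)
    chromosome_summary(m, physical_length_mb = len_of(m))))
  rownames(summaries) <- NULL
  genome <- genome_summary(summaries, assembly_length_mb = assembly_length_mb)
  list(qc = qc$report, groups = grp$groups, unassigned = grp$unassigned,
       maps = maps, summaries = summaries, genome = genome)
}

#' Simulate the reference single-family mapping study and recover its maps
#'
#' Convenience wrapper used for validation: simulates one full-sib family
#' (default 105 offspring, 200 markers per chromosome, no noise) on the
#' published per-chromosome physical and sex-specific map lengths, runs
#' [linkage_pipeline()], and returns the pipeline result together with the
#' simulation truth and a [recovery_report()].
#'
#' @param n_offspring,n_markers_per_chrom Family size and marker density.
#' @param species Which published chromosome table provides the truth.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the simulation.
#' @param lod_threshold,... Passed to [linkage_pipeline()].
#' @return List with `pipeline`, `truth` and `recovery`.
#' @export
simulate_and_map <- function(n_offspring = 105, n_markers_per_chrom = 200,
                             species = "palmata", noise = noise_model(),
                             seed = 1L, lod_threshold = 11, ...) {
  models <- acropora_chromosome_models(species)
  parents <- simulate_parents(n_markers_per_chrom, models, seed = seed)
  fam <- simulate_family(family_design("F1", "dam", "sire", n_offspring),
                         parents, models, noise = noise, seed = seed + 1L)
  chrom_lengths <- data.frame(
    chromosome = vapply(models, `[[`, "", "name"),
    length_bp = vapply(models, `[[`, 0, "physical_length"))
  res <- linkage_pipeline(fam$geno, lod_threshold = lod_threshold,
                          chrom_lengths = chrom_lengths, ...)
  list(pipeline = res, truth = fam$truth,
       recovery = recovery_report(res$maps, fam$truth))
}
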