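#' spotTCR: spot-resolved TCR clonotype mapping for spatial transcriptomics
#'
#' See the package README and the methods vignette for the scientific
#' background; the pipeline surface is [run_extract()], [run_link()],
#' [run_stats()] and [run_repertoire()], each a thin composition of the
#' exported building blocks.
#'
#' @importFrom data.table data.table setorder .N
#' @keywords internal
"_PACKAGE"

#' Read a pipeline configuration YAML
#'
#' @param path YAML file; keys mirror the arguments of the `run_*`
#'   functions (`paths:` for inputs, flat keys for parameters).
#' @return Named list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(barcode_len = 16L, umi_len = 12L, pitch_um = 100,
                   tumor_labels = "tumor", cefx_min_count = 2,
                   cefx_min_ratio = 5, gene_min_total = 10,
                   gene_min_spots = 3, top_n = 10L, seed = 1L)
  utils::modifyList(defaults, cfg)
}

echo_config <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing input: ", what, " (", if (is.null(path)) "unset"
         else path, ")")
  path
}

#' Extract the clone-by-spot UMI matrix from paired FASTQ
#'
#' Composes read-1 parsing, barcode correction and UMI deduplication into
#' the spatial clone matrix. Clone assignments come either from an external
#' caller's read export (`clone_map` path) or from the built-in lite caller
#' run on read 2 (`refs`).
#'
#' @param r1,r2 FASTQ(.gz) paths (read 1: barcode + UMI; read 2: insert).
#'   `r2` is only needed when calling clones internally.
#' @param whitelist Whitelist path or barcode vector.
#' @param clone_map Optional path to a read-to-clone TSV
#'   ([load_clone_read_map()]).
#' @param refs Optional segment reference for the lite caller (used when
#'   `clone_map` is NULL).
#' @param out_dir Optional directory: matrix, clone table and QC TSVs are
#'   written there.
#' @param barcode_len,umi_len Read-1 structure.
#' @return The [build_spatial_clone_matrix()] result.
#' @export
run_extract <- function(r1, whitelist, r2 = NULL, clone_map = NULL,
                        refs = NULL, out_dir = NULL,
                        barcode_len = 16L, umi_len = 12L) {
  require_file(r1, "read-1 FASTQ")
  if (is.character(whitelist) && length(whitelist) == 1L)
    require_file(whitelist, "barcode whitelist")
  wl <- barcode_whitelist(whitelist)
  clone_table <- NULL
  if (!is.null(clone_map)) {
    cmap <- load_clone_read_map(require_file(clone_map, "clone read map"))
  } else {
    if (is.null(refs)) stop("missing input: clone read map or segment ",
                            "reference for the lite caller")
    require_file(r2, "read-2 FASTQ")
    calls <- call_clones_from_fastq(r2, refs)
    cmap <- calls$read_map
    clone_table <- calls$clone_table
  }
  mat <- build_spatial_clone_matrix(r1, cmap, wl, barcode_len, umi_len,
                                    clone_table = clone_table)
  if (!is.null(out_dir)) {
    write_clone_matrix(mat, out_dir)
    write_qc_report(mat$qc, file.path(out_dir, "extract_qc.tsv"))
  }
  mat
}

#' Link spatial clones to single-cell phenotypes
#'
#' Joins the spatial clone matrix to the cell table on family-level clone
#' identity and classifies each spatial clone as AD / BC / ambiguous /
#' unclassified from the metacluster membership of its cells.
#'
#' @param mat Spatial clone matrix ([run_extract()] result).
#' @param cells Cell table (after [rescue_beta_by_alpha()]).
#' @param out_dir Optional output directory for the per-clone TSV.
#' @return [classify_clone_phenotype()] table covering every spatial clone;
#'   clones absent from the cell table are `"unclassified"`.
#' @export
run_link <- function(mat, cells, out_dir = NULL) {
  spatial_clones <- sort(unique(mat$counts$clone_id))
  shared <- intersect(spatial_clones, cells$clone_id)
  if (length(shared) == 0L)
    warning("no clones shared between spatial and single-cell data")
  phen <- classify_clone_phenotype(cells, clone_id = spatial_clones)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(phen, file.path(out_dir, "clone_phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  phen
}

#' Spatial localization statistics for classified clones
#'
#' Computes per-clone tumor fractions, the region-resolved UMI distribution,
#' distance-to-border ECDFs and the nonparametric group contrasts
#' (Mann-Whitney on per-clone tumor fractions, Kolmogorov-Smirnov on
#' UMI-expanded border distances), plus the expanded-clone table. Both
#' aggregation conventions for the expanded-clone tumor share are reported:
#' pooled UMIs and the median per-clone fraction. Ambiguous / unclassified
#' clones are excluded from the two-group tests but kept in the summary.
#'
#' @param mat Spatial clone matrix.
#' @param phenotype [run_link()] table.
#' @param grid Spot grid.
#' @param top_n Expansion criterion for the expanded-clone table.
#' @param spot_totals Optional per-spot gene-expression totals for the
#'   reference line.
#' @param out_dir Optional output directory (summary, ECDF and test TSVs).
#' @return list: `summary`, `region_distribution`, `ecdf_ad`, `ecdf_bc`,
#'   `ks`, `mann_whitney`, `expanded`, `pooled_tumor_share`,
#'   `median_tumor_fraction`.
#' @export
run_stats <- function(mat, phenotype, grid, top_n = 10L,
                      spot_totals = NULL, out_dir = NULL) {
  summary <- clone_spatial_summary(mat, grid, phenotype)
  ad <- summary$clone_id[summary$call %in% "AD"]
  bc <- summary$clone_id[summary$call %in% "BC"]
  region <- region_umi_distribution(phenotype, mat, grid)
  ks <- mw <- NULL
  ecdf_ad <- ecdf_bc <- NULL
  if (length(ad) && length(bc)) {
    fa <- summary$tumor_fraction[summary$call %in% "AD"]
    fb <- summary$tumor_fraction[summary$call %in% "BC"]
    mw <- mann_whitney_u(fa[!is.na(fa)], fb[!is.na(fb)])
    da <- umi_border_distances(ad, mat, grid)
    db <- umi_border_distances(bc, mat, grid)
    if (length(da)) ecdf_ad <- distance_ecdf(da)
    if (length(db)) ecdf_bc <- distance_ecdf(db)
    if (length(da) && length(db)) ks <- ks_two_sample(da, db)
  } else {
    message("fewer than two phenotype groups: group tests skipped")
  }
  expanded <- expanded_clone_localization(mat, phenotype, grid,
                                          top_n = top_n,
                                          spot_totals = spot_totals)
  pooled <- function(ids) {
    sub <- summary[summary$clone_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_real_)
    100 * sum(sub$umis_in_tumor) / sum(sub$total_umis)
  }
  exp_ad <- expanded$clone_id[expanded$call %in% "AD"]
  exp_bc <- expanded$clone_id[expanded$call %in% "BC"]
  out <- list(
    summary = summary, region_distribution = region,
    ecdf_ad = ecdf_ad, ecdf_bc = ecdf_bc, ks = ks, mann_whitney = mw,
    expanded = expanded,
    pooled_tumor_share = c(AD = pooled(exp_ad), BC = pooled(exp_bc)),
    median_tumor_fraction = c(
      AD = stats::median(expanded$tumor_fraction[expanded$call %in% "AD"],
                         na.rm = TRUE),
      BC = stats::median(expanded$tumor_fraction[expanded$call %in% "BC"],
                         na.rm = TRUE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "clone_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(region))
      utils::write.table(region, file.path(out_dir, "region_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- data.frame(
      test = c("mann_whitney", "kolmogorov_smirnov"),
      statistic = c(if (is.null(mw)) NA else mw$U,
                    if (is.null(ks)) NA else ks$statistic),
      p_value = c(if (is.null(mw)) NA else mw$p_value,
                  if (is.null(ks)) NA else ks$p_value),
      n_x = c(if (is.null(mw)) NA else mw$n_x,
              if (is.null(ks)) NA else ks$n_x),
      n_y = c(if (is.null(mw)) NA else mw$n_y,
              if (is.null(ks)) NA else ks$n_y))
    utils::write.table(tests, file.path(out_dir, "tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in c("ecdf_ad", "ecdf_bc"))
      if (!is.null(out[[nm]]))
        utils::write.table(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expanded, file.path(out_dir, "expanded_clones.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Repertoire diversity, overlap and specificity bundle
#'
#' @param reps Named list of repertoires (populations or metaclusters).
#' @param cefx_pos,cefx_neg Optional IFN-gamma positive/negative
#'   repertoires; when given, the CEFX-specific clone set and per-population
#'   bystander fractions are computed.
#' @param min_size Populations below this total are flagged in the output.
#' @param out_dir Optional output directory.
#' @return list: `shannon` (named vector), `overlap`
#'   ([pairwise_overlap_matrix()]), `rank_cumulative` (list of tables),
#'   `cefx_specific`, `bystander_pct` (named vector), `flagged`.
#' @export
run_repertoire <- function(reps, cefx_pos = NULL, cefx_neg = NULL,
                           min_size = 10L, out_dir = NULL) {
  stopifnot(length(reps) >= 1L)
  shannon <- vapply(reps, shannon_index, 0)
  overlap <- if (length(reps) >= 2L) pairwise_overlap_matrix(reps) else NULL
  ranks <- lapply(reps, clone_rank_cumulative)
  flagged <- names(reps)[vapply(reps, function(r) r$total, 0) < min_size]
  specific <- NULL
  bystander <- NULL
  if (!is.null(cefx_pos) && !is.null(cefx_neg)) {
    specific <- cefx_specific_clones(cefx_pos, cefx_neg)
    bystander <- vapply(reps, function(r)
      100 * sum(r$counts[names(r$counts) %in% specific]) / r$total, 0)
  }
  out <- list(shannon = shannon, overlap = overlap,
              rank_cumulative = ranks, cefx_specific = specific,
              bystander_pct = bystander, flagged = flagged)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(population = names(shannon), shannon = unname(shannon)),
      file.path(out_dir, "shannon.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(overlap))
      utils::write.table(overlap, file.path(out_dir, "overlap_matrix.tsv"),
                         sep = "\t", quote = FALSE)
    if (!is.null(specific))
      writeLines(specific, file.path(out_dir, "cefx_specific_clones.txt"))
  }
  out
}
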