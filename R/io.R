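read_delim_checked <- function(path, required, sep, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  present <- vapply(required, function(alts) any(alts %in% names(df)), TRUE)
  if (!all(present)) {
    missing <- vapply(required[!present], `[`, "", 1L)
    stop(what, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

pick_col <- function(df, alts) {
  hit <- alts[alts %in% names(df)][1]
  df[[hit]]
}

#' Read a 10x-style filtered contig annotation table
#'
#' Consumes the `filtered_contig_annotations.csv` dialect (columns used:
#' `barcode`, `chain`, `v_gene`, `j_gene`, `cdr3`, `cdr3_nt`, `productive`,
#' `is_cell`) and returns the cell and alpha-chain tables used by the
#' clonotype operations. Only productive contigs of called cells are kept.
#' Cells whose productive TRB contigs name more than one distinct clonotype
#' are left with an undetermined beta (candidates for alpha rescue).
#'
#' @param path CSV path.
#' @param metacluster Optional named vector (names = barcodes) of metacluster
#'   labels to attach; unknown barcodes become `"unassigned"`.
#' @param patient,compartment Labels stored on every cell.
#' @return list with `cells` (see [cell_table()]) and `alphas`.
#' @export
read_contig_annotations <- function(path, metacluster = NULL,
                                    patient = "p1", compartment = "tumor") {
  df <- read_delim_checked(
    path,
    list("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt"),
    sep = ",", what = "contig annotation")
  truthy <- function(x) {
    if (is.logical(x)) x else tolower(as.character(x)) %in% c("true", "t", "1")
  }
  if ("productive" %in% names(df)) df <- df[truthy(df$productive), ]
  if ("is_cell" %in% names(df)) df <- df[truthy(df$is_cell), ]

  trb <- df[df$chain == "TRB" & grepl("^TRBV", df$v_gene) &
              grepl("^TRBJ", df$j_gene), , drop = FALSE]
  keys <- build_clone_key(trb$v_gene, trb$j_gene, trb$cdr3)
  kept <- is_productive_cdr3(trb$cdr3)
  trb <- trb[kept, , drop = FALSE]
  trb$clone_id <- keys$clone_id
  per_cell <- tapply(trb$clone_id, trb$barcode,
                     function(z) if (length(unique(z)) == 1L) z[[1]]
                     else NA_character_)

  tra <- df[df$chain == "TRA", , drop = FALSE]
  alphas <- data.frame(cell_id = tra$barcode, v_gene = tra$v_gene,
                       j_gene = tra$j_gene, cdr3_aa = tra$cdr3,
                       cdr3_nt = tra$cdr3_nt, stringsAsFactors = FALSE)

  ids <- sort(unique(df$barcode))
  clone <- as.character(per_cell[ids])
  mc <- if (is.null(metacluster)) "unassigned" else {
    m <- as.character(metacluster[ids])
    m[is.na(m)] <- "unassigned"
    m
  }
  cells <- cell_table(ids, clone, mc, patient, compartment)
  list(cells = cells, alphas = alphas)
}

#' Read an Adaptive-style bulk TCRbeta count table
#'
#' Tab-separated; columns used: `amino_acid` (or `cdr3_amino_acid`),
#' `v_family` (or `v_gene`), `j_family` (or `j_gene`), and `templates` (or
#' `count`). Rows with non-productive CDR3s are dropped.
#'
#' @param path TSV path.
#' @param label Population label of the returned repertoire.
#' @return A [repertoire()] keyed by family-level clone ids.
#' @export
read_adaptive_tsv <- function(path, label = basename(path)) {
  df <- read_delim_checked(
    path,
    list(c("amino_acid", "cdr3_amino_acid"), c("v_family", "v_gene"),
         c("j_family", "j_gene"), c("templates", "count")),
    sep = "\t", what = "bulk TCR")
  cdr3 <- pick_col(df, c("amino_acid", "cdr3_amino_acid"))
  v <- pick_col(df, c("v_family", "v_gene"))
  j <- pick_col(df, c("j_family", "j_gene"))
  n <- pick_col(df, c("templates", "count"))
  ok <- is_productive_cdr3(cdr3) & !is.na(n) & n > 0
  keys <- build_clone_key(v[ok], j[ok], cdr3[ok])
  aggregate_repertoire(keys$clone_id, as.integer(n[ok]), label)
}

#' Read a VDJdb-style paired-chain TSV
#'
#' Long format with one row per chain; rows sharing a `complex.id` pair an
#' alpha with a beta. Columns used: `complex.id`, `gene` (TRA/TRB), `cdr3`,
#' `v.segm`, `j.segm`, `antigen.epitope`, `antigen.species`.
#'
#' @param path TSV path.
#' @return data.frame with one row per paired record: `cdr3_alpha`,
#'   `cdr3_beta`, `trav`, `traj`, `trbv`, `trbj`, `antigen_epitope`,
#'   `antigen_species`.
#' @export
read_vdjdb_tsv <- function(path) {
  df <- read_delim_checked(
    path, list("complex.id", "gene", "cdr3", "v.segm", "j.segm"),
    sep = "\t", what = "VDJdb")
  df <- df[df$complex.id != 0 & !is.na(df$complex.id), , drop = FALSE]
  a <- df[df$gene == "TRA", , drop = FALSE]
  b <- df[df$gene == "TRB", , drop = FALSE]
  shared <- intersect(a$complex.id, b$complex.id)
  a <- a[match(shared, a$complex.id), , drop = FALSE]
  b <- b[match(shared, b$complex.id), , drop = FALSE]
  out <- data.frame(
    complex_id = shared,
    cdr3_alpha = a$cdr3, cdr3_beta = b$cdr3,
    trav = a$v.segm, traj = a$j.segm, trbv = b$v.segm, trbj = b$j.segm,
    stringsAsFactors = FALSE)
  out$antigen_epitope <- if ("antigen.epitope" %in% names(b))
    b$antigen.epitope else NA_character_
  out$antigen_species <- if ("antigen.species" %in% names(b))
    b$antigen.species else NA_character_
  out
}

#' Read a Visium-style tissue positions table
#'
#' Accepts the headerless `tissue_positions_list.csv` dialect (6 columns:
#' barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres) or the same columns with a header line.
#'
#' @param path CSV path.
#' @return data.frame with those six columns, `in_tissue` logical.
#' @export
read_tissue_positions <- function(path) {
  if (!file.exists(path)) stop("tissue positions file not found: ", path)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stop("tissue positions file ", path, " lacks required column(s): ",
         paste(cols[seq(ncol(df) + 1L, 6L)], collapse = ", "))
  names(df)[1:6] <- cols
  df$in_tissue <- as.logical(as.integer(df$in_tissue))
  df[, cols]
}

#' Read a spot-to-region annotation table
#'
#' @param path CSV with columns `barcode` and `region` (as exported from
#'   interactive cluster annotation).
#' @return data.frame with `barcode`, `region`.
#' @export
read_region_annotations <- function(path) {
  df <- read_delim_checked(path, list("barcode", "region"), sep = ",",
                           what = "region annotation")
  df[, c("barcode", "region")]
}

#' Build a spot grid from positions and region annotations
#'
#' Array coordinates follow the platform's even/odd hexagonal-offset
#' convention (adjacent spots in one row are two `array_col` units apart).
#' Spot centers are placed at `x = array_col * pitch/2`,
#' `y = array_row * pitch * sqrt(3)/2`, so any two neighboring spots are
#' `pitch` micrometers apart.
#'
#' @param positions Output of [read_tissue_positions()] (or a data.frame with
#'   those columns).
#' @param regions Optional output of [read_region_annotations()].
#' @param tumor_labels Character vector of region labels counted as tumor
#'   parenchyma.
#' @param pitch_um Center-to-center spot distance in micrometers.
#' @return data.frame (`spot_grid`): `barcode`, `array_row`, `array_col`,
#'   `x`, `y` (micrometers), `in_tissue`, `region`, `is_tumor`.
#' @export
build_spot_grid <- function(positions, regions = NULL,
                            tumor_labels = "tumor", pitch_um = 100) {
  if (anyDuplicated(positions$barcode))
    stop("duplicate spot barcodes in positions table")
  g <- data.frame(
    barcode = positions$barcode,
    array_row = positions$array_row, array_col = positions$array_col,
    x = positions$array_col * pitch_um / 2,
    y = positions$array_row * pitch_um * sqrt(3) / 2,
    in_tissue = positions$in_tissue,
    stringsAsFactors = FALSE)
  g$region <- NA_character_
  if (!is.null(regions))
    g$region <- regions$region[match(g$barcode, regions$barcode)]
  g$is_tumor <- !is.na(g$region) & g$region %in% tumor_labels & g$in_tissue
  class(g) <- c("spot_grid", class(g))
  g
}

#' Write a clone-by-spot matrix as TSV triplets and MatrixMarket export
#'
#' @param mat Result of [build_spatial_clone_matrix()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_clone_matrix <- function(mat, dir, prefix = "spatial_tcr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_tsv <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  utils::write.table(mat$counts, p_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_clones <- file.path(dir, paste0(prefix, "_clones.tsv"))
  utils::write.table(mat$clone_table, p_clones, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clones <- sort(unique(mat$counts$clone_id))
  spots <- sort(unique(mat$counts$barcode))
  sm <- Matrix::sparseMatrix(
    i = match(mat$counts$clone_id, clones),
    j = match(mat$counts$barcode, spots),
    x = mat$counts$umi_count, dims = c(length(clones), length(spots)))
  p_mtx <- file.path(dir, paste0(prefix, "_matrix.mtx"))
  Matrix::writeMM(sm, p_mtx)
  writeLines(clones, file.path(dir, paste0(prefix, "_matrix.rows")))
  writeLines(spots, file.path(dir, paste0(prefix, "_matrix.cols")))
  invisible(c(p_tsv, p_clones, p_mtx))
}

#' Write the read-fate QC report of an extraction run
#'
#' @param qc Named integer vector of read fates.
#' @param path Output TSV path.
#' @export
write_qc_report <- function(qc, path) {
  df <- data.frame(category = names(qc), reads = as.integer(qc),
                   stringsAsFactors = FALSE)
  total <- sum(df$reads)
  df$fraction <- if (total > 0) df$reads / total else 0
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
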