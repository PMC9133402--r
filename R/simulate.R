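CODON_OF_AA <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTC", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "AGC", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT")

reverse_translate <- function(aa) {
  vapply(strsplit(aa, ""), function(ch)
    paste(CODON_OF_AA[ch], collapse = ""), "")
}

random_nt <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Generate a spot-barcode whitelist with guaranteed separation
#'
#' Random fixed-length barcodes accepted by rejection sampling so that every
#' pair is at Hamming distance at least `min_dist`; with `min_dist = 3` the
#' one-mismatch neighborhoods of distinct barcodes are disjoint and
#' single-substitution correction can never cross spots.
#'
#' @param n Number of barcodes.
#' @param barcode_len Barcode length.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return Character vector of barcodes.
#' @export
simulate_barcode_whitelist <- function(n, barcode_len = 16L, min_dist = 3L) {
  alpha <- c("A", "C", "G", "T")
  acc <- matrix("", nrow = barcode_len, ncol = 0)
  tries <- 0L
  while (ncol(acc) < n) {
    tries <- tries + 1L
    if (tries > 50L * n) stop("whitelist rejection sampling failed")
    cand <- sample(alpha, barcode_len, replace = TRUE)
    if (ncol(acc) == 0L || all(colSums(acc != cand) >= min_dist))
      acc <- cbind(acc, cand)
  }
  apply(acc, 2L, paste, collapse = "")
}

#' Simulate a hexagonal spot grid with a contiguous tumor region
#'
#' Spots sit on a hexagonal-offset lattice (the platform's even/odd array
#' convention); spots within `tumor_radius_um` of the central spot are
#' labeled `"tumor"`, the rest `"stroma"`. All spots are in tissue.
#'
#' @param n_rows,n_cols Grid dimensions (spots per row/column).
#' @param tumor_radius_um Disc radius in micrometers (0 labels only the
#'   center spot).
#' @param pitch_um Center-to-center spot spacing.
#' @param barcode_len Whitelist barcode length.
#' @param min_dist Minimum pairwise whitelist Hamming distance.
#' @return A [build_spot_grid()]-style data.frame; the underlying positions
#'   table is attached as attribute `"positions"`.
#' @export
simulate_tissue <- function(n_rows = 30L, n_cols = 30L,
                            tumor_radius_um = 700, pitch_um = 100,
                            barcode_len = 16L, min_dist = 3L) {
  if (n_rows < 1L || n_cols < 1L || tumor_radius_um < 0)
    stop("degenerate tissue geometry")
  array_row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  array_col <- rep(seq_len(n_cols) - 1L, times = n_rows) * 2L +
    array_row %% 2L
  n <- n_rows * n_cols
  barcodes <- simulate_barcode_whitelist(n, barcode_len, min_dist)
  positions <- data.frame(
    barcode = barcodes, in_tissue = TRUE,
    array_row = array_row, array_col = array_col,
    pxl_row_in_fullres = round(array_row * pitch_um * sqrt(3) / 2),
    pxl_col_in_fullres = round(array_col * pitch_um / 2),
    stringsAsFactors = FALSE)
  x <- array_col * pitch_um / 2
  y <- array_row * pitch_um * sqrt(3) / 2
  center <- which.min((x - mean(range(x)))^2 + (y - mean(range(y)))^2)
  d <- sqrt((x - x[center])^2 + (y - y[center])^2)
  regions <- data.frame(barcode = barcodes,
                        region = ifelse(d <= tumor_radius_um,
                                        "tumor", "stroma"),
                        stringsAsFactors = FALSE)
  grid <- build_spot_grid(positions, regions, tumor_labels = "tumor",
                          pitch_um = pitch_um)
  attr(grid, "positions") <- positions
  attr(grid, "regions") <- regions
  grid
}

#' Simulate a clone repertoire with phenotypes and abundances
#'
#' Clone keys use the bundled toy segment reference with random CDR3s
#' (conserved C...F, 8-16 amino acids). Phenotype labels AD / BC are drawn
#' independently per clone; abundances follow a Zipf law over clone ranks
#' (exponent 0 = uniform) unless a constant `umis_per_clone` is requested.
#'
#' @param n_clones Number of distinct clonotypes.
#' @param zipf_exponent Zipf abundance exponent (UMIs are multinomial over
#'   weights `rank^-exponent`).
#' @param total_umis Total planted UMIs (used with `zipf_exponent`).
#' @param umis_per_clone If non-NULL, every clone receives exactly this many
#'   UMIs and the Zipf law is ignored.
#' @param p_ad Probability that a clone is an A/D-phenotype clone.
#' @param refs Segment reference (default [toy_segment_reference()]).
#' @return data.frame: `clone_id`, `v_gene`, `j_gene`, `cdr3_aa`, `cdr3_nt`,
#'   `phenotype`, `n_umis`.
#' @export
simulate_repertoire <- function(n_clones, zipf_exponent = 1,
                                total_umis = 50L * n_clones,
                                umis_per_clone = NULL, p_ad = 0.5,
                                refs = toy_segment_reference()) {
  stopifnot(n_clones >= 1L)
  vrefs <- refs[refs$type == "V", ]
  jrefs <- refs[refs$type == "J", ]
  seen <- character(0)
  v <- character(n_clones); j <- character(n_clones)
  aa <- character(n_clones)
  for (i in seq_len(n_clones)) {
    repeat {
      vi <- sample(nrow(vrefs), 1L); ji <- sample(nrow(jrefs), 1L)
      mid <- paste(sample(AA_ALPHABET, sample(6:14, 1L), replace = TRUE),
                   collapse = "")
      cdr3 <- paste0("C", mid, "F")
      id <- clone_id_string(normalize_gene_family(vrefs$name[vi]),
                            normalize_gene_family(jrefs$name[ji]), cdr3)
      if (!id %in% seen) break
    }
    seen[i] <- id
    v[i] <- vrefs$name[vi]; j[i] <- jrefs$name[ji]; aa[i] <- cdr3
  }
  n_umis <- if (!is.null(umis_per_clone)) {
    rep(as.integer(umis_per_clone), n_clones)
  } else {
    w <- seq_len(n_clones)^(-zipf_exponent)
    as.integer(stats::rmultinom(1L, total_umis, w / sum(w)))
  }
  data.frame(
    clone_id = seen, v_gene = v, j_gene = j, cdr3_aa = aa,
    cdr3_nt = reverse_translate(aa),
    phenotype = ifelse(stats::runif(n_clones) < p_ad, "AD", "BC"),
    n_umis = n_umis, stringsAsFactors = FALSE)
}

#' Place clone UMIs on the tissue with phenotype-dependent tumor preference
#'
#' Each UMI of a clone lands on a tumor spot with probability
#' `p_tumor[phenotype]`, uniformly within the chosen compartment; UMI
#' sequences are distinct within each (clone, spot).
#'
#' @param clones [simulate_repertoire()] table.
#' @param grid [simulate_tissue()] grid.
#' @param p_tumor Named vector of tumor-placement probabilities per
#'   phenotype.
#' @param umi_len UMI length.
#' @return list with `placements` (one row per UMI: `clone_id`, `barcode`,
#'   `umi`) and `counts` (the planted clone-by-spot UMI matrix).
#' @export
simulate_spatial_umis <- function(clones, grid,
                                  p_tumor = c(AD = 0.8, BC = 0.2),
                                  umi_len = 12L) {
  tum <- grid$barcode[grid$is_tumor]
  str <- grid$barcode[!grid$is_tumor]
  p <- p_tumor[clones$phenotype]
  if (anyNA(p)) stop("p_tumor lacks an entry for some phenotype")
  rows <- rep(seq_len(nrow(clones)), clones$n_umis)
  in_tumor <- stats::runif(length(rows)) < p[rows]
  if (any(in_tumor) && length(tum) == 0L)
    stop("tumor compartment has no spots")
  if (any(!in_tumor) && length(str) == 0L)
    stop("non-tumor compartment has no spots")
  barcode <- character(length(rows))
  barcode[in_tumor] <- sample(tum, sum(in_tumor), replace = TRUE)
  barcode[!in_tumor] <- sample(str, sum(!in_tumor), replace = TRUE)
  umi <- random_nt(length(rows), umi_len)
  placements <- data.frame(clone_id = clones$clone_id[rows],
                           barcode = barcode, umi = umi,
                           stringsAsFactors = FALSE)
  # enforce UMI distinctness within (clone, spot)
  key <- function(d) paste(d$clone_id, d$barcode, d$umi, sep = "\r")
  repeat {
    dup <- duplicated(key(placements))
    if (!any(dup)) break
    placements$umi[dup] <- random_nt(sum(dup), umi_len)
  }
  dt <- data.table::data.table(placements)
  counts <- dt[, list(umi_count = .N), by = c("clone_id", "barcode")]
  data.table::setorder(counts, clone_id, barcode)
  list(placements = placements, counts = as.data.frame(counts))
}

mutate_region <- function(seqs, from, to, rate) {
  if (rate <= 0) return(seqs)
  width <- to - from + 1L
  n_err <- stats::rbinom(length(seqs), width, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(width, n_err[i]) + from - 1L
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seqs
}

write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Emit paired FASTQ reads for planted UMI placements
#'
#' Read 1 carries spot barcode + UMI (+ random padding); read 2 is a window
#' of the clone's V--CDR3--J transcript starting at a per-read primer
#' position (emulating a pool of V-segment forward primers). Substitution
#' errors are applied at configurable per-base rates; no indels are
#' simulated.
#'
#' @param placements `placements` from [simulate_spatial_umis()].
#' @param clones [simulate_repertoire()] table.
#' @param refs Segment reference.
#' @param r1_path,r2_path Output FASTQ paths (`.gz` for gzip).
#' @param reads_per_umi Constant number of reads per UMI molecule.
#' @param err_barcode,err_umi,err_insert Per-base substitution rates for the
#'   barcode, UMI and read-2 insert.
#' @param primer_starts Candidate 1-based primer start offsets within the V
#'   segment, sampled uniformly per read.
#' @param read2_len Read-2 length (clipped at the transcript end).
#' @param padding Extra random bases appended to read 1.
#' @return data.frame truth map: `read_id`, `clone_id`, `barcode`, `umi`.
#' @export
emit_fastq <- function(placements, clones, refs = toy_segment_reference(),
                       r1_path, r2_path, reads_per_umi = 3L,
                       err_barcode = 0, err_umi = 0, err_insert = 0,
                       primer_starts = 1:15, read2_len = 150L,
                       padding = 0L) {
  transcript <- clone_transcripts(clones, refs)
  rows <- rep(seq_len(nrow(placements)), each = reads_per_umi)
  n <- length(rows)
  read_id <- sprintf("sim%08d", seq_len(n))
  barcode <- placements$barcode[rows]
  umi <- placements$umi[rows]
  clone <- placements$clone_id[rows]
  blen <- nchar(barcode[1]); ulen <- nchar(umi[1])
  r1 <- paste0(barcode, umi,
               if (padding > 0L) random_nt(n, padding) else "")
  r1 <- mutate_region(r1, 1L, blen, err_barcode)
  r1 <- mutate_region(r1, blen + 1L, blen + ulen, err_umi)
  tr <- transcript[clone]
  start <- sample(primer_starts, n, replace = TRUE)
  r2 <- substr(tr, start, pmin(nchar(tr), start + read2_len - 1L))
  if (err_insert > 0)
    r2 <- vapply(seq_len(n), function(i)
      mutate_region(r2[i], 1L, nchar(r2[i]), err_insert), "")
  write_fastq(read_id, r1, r1_path)
  write_fastq(read_id, r2, r2_path)
  data.frame(read_id = read_id, clone_id = clone, barcode = barcode,
             umi = umi, stringsAsFactors = FALSE)
}

#' Full V--CDR3--J transcript of each clone
#'
#' @param clones [simulate_repertoire()] table.
#' @param refs Segment reference.
#' @return Named character vector (names = clone ids).
#' @keywords internal
clone_transcripts <- function(clones, refs) {
  v <- refs[match(clones$v_gene, refs$name), ]
  j <- refs[match(clones$j_gene, refs$name), ]
  if (anyNA(v$seq) || anyNA(j$seq))
    stop("clone table references unknown segments")
  stats::setNames(paste0(substr(v$seq, 1L, v$anchor_start - 1L),
                         clones$cdr3_nt,
                         substr(j$seq, 4L, nchar(j$seq))),
                  clones$clone_id)
}

#' Simulate a single-cell table consistent with clone phenotypes
#'
#' Cells of an AD clone sit in metaclusters A or D with probability
#' `purity` (B or C otherwise) and vice versa for BC clones.
#'
#' @param clones [simulate_repertoire()] table.
#' @param cells_per_clone Cells per clone (recycled).
#' @param purity Probability that a cell's metacluster matches its clone's
#'   phenotype.
#' @param patient,compartment Labels.
#' @return A [cell_table()].
#' @export
simulate_cell_table <- function(clones, cells_per_clone = 5L, purity = 1,
                                patient = "p1", compartment = "tumor") {
  cells_per_clone <- rep_len(cells_per_clone, nrow(clones))
  rows <- rep(seq_len(nrow(clones)), cells_per_clone)
  n <- length(rows)
  match_phen <- stats::runif(n) < purity
  own <- clones$phenotype[rows]
  group <- ifelse(match_phen, own, ifelse(own == "AD", "BC", "AD"))
  mc <- ifelse(group == "AD",
               sample(c("A", "D"), n, replace = TRUE),
               sample(c("B", "C"), n, replace = TRUE))
  cell_table(sprintf("cell%06d", seq_len(n)), clones$clone_id[rows], mc,
             patient, compartment)
}

#' Simulate IFN-gamma capture count tables with designated specific clones
#'
#' Builds IFN-gamma positive / negative sorted TCRbeta count tables in which
#' the designated clones satisfy the specificity rule by construction
#' (count >= 2 in the positive sort, frequency >= 5-fold enriched) and every
#' other clone violates at least one clause. Both tables are padded with a
#' background clone to a common total so frequency ratios equal count
#' ratios.
#'
#' @param clones [simulate_repertoire()] table.
#' @param n_specific Number of designated CEFX-specific clones.
#' @param total Common total template count of each table.
#' @return list with repertoires `pos`, `neg`, and `specific` (designated
#'   clone ids, sorted).
#' @export
simulate_cefx_tables <- function(clones, n_specific = 5L, total = 1000L) {
  ids <- clones$clone_id
  stopifnot(n_specific <= length(ids))
  spec <- sort(sample(ids, n_specific))
  rest <- setdiff(ids, spec)
  pos <- stats::setNames(integer(length(ids)), ids)
  neg <- pos
  # designated clones: count >= 2, >= 5-fold enrichment
  pos[spec] <- sample(10:20, length(spec), replace = TRUE)
  neg[spec] <- ifelse(stats::runif(length(spec)) < 0.5, 0L,
                      pmax(0L, pos[spec] %/% 6L))
  if (length(rest)) {
    flavor <- sample(c("low_count", "low_ratio", "neg_only"), length(rest),
                     replace = TRUE)
    pos[rest][flavor == "low_count"] <- 1L
    neg[rest][flavor == "low_count"] <- 0L
    pos[rest][flavor == "low_ratio"] <- 4L
    neg[rest][flavor == "low_ratio"] <- 2L
    pos[rest][flavor == "neg_only"] <- 0L
    neg[rest][flavor == "neg_only"] <- 3L
  }
  stopifnot(sum(pos) + 2L <= total, sum(neg) + 2L <= total)
  filler <- clone_id_string("TRBV28", "TRBJ1", "CASSGGGGNTEAFF")
  pos[filler] <- total - sum(pos)
  neg[filler] <- total - sum(neg)
  list(pos = repertoire(pos[pos > 0], "IFNg+"),
       neg = repertoire(neg[neg > 0], "IFNg-"),
       specific = spec)
}

#' Simulate a complete spatial TCR dataset on disk
#'
#' Orchestrates tissue, repertoire, UMI placement, FASTQ emission and the
#' companion tables, writing every file a real run would consume, plus a
#' YAML echo of the resolved configuration.
#'
#' @param out_dir Output directory.
#' @param seed Random seed (fixed seed gives byte-identical outputs).
#' @param n_rows,n_cols,tumor_radius_um,pitch_um Tissue geometry.
#' @param n_clones,zipf_exponent,total_umis,umis_per_clone,p_ad Repertoire.
#' @param p_tumor Tumor placement probability per phenotype.
#' @param reads_per_umi,err_barcode,err_umi,err_insert Read emission.
#' @param barcode_len,umi_len Read-1 structure.
#' @param gzip Write gzipped FASTQ.
#' @param cells_per_clone,purity Cell table.
#' @param n_specific IFN-gamma capture designated clones.
#' @return Invisibly, the ground truth: grid, clones, placements, planted
#'   counts, truth read map, cells, cefx tables, and the file paths.
#' @export
simulate_spatial_dataset <- function(out_dir, seed = 1L,
                                     n_rows = 30L, n_cols = 30L,
                                     tumor_radius_um = 700, pitch_um = 100,
                                     n_clones = 50L, zipf_exponent = 1,
                                     total_umis = 2500L,
                                     umis_per_clone = NULL, p_ad = 0.5,
                                     p_tumor = c(AD = 0.8, BC = 0.2),
                                     reads_per_umi = 3L,
                                     err_barcode = 0, err_umi = 0,
                                     err_insert = 0,
                                     barcode_len = 16L, umi_len = 12L,
                                     gzip = FALSE,
                                     cells_per_clone = 5L, purity = 1,
                                     n_specific = 5L) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- toy_segment_reference()
  grid <- simulate_tissue(n_rows, n_cols, tumor_radius_um, pitch_um,
                          barcode_len)
  clones <- simulate_repertoire(n_clones, zipf_exponent, total_umis,
                                umis_per_clone, p_ad, refs)
  n_specific <- min(n_specific, n_clones)
  placed <- simulate_spatial_umis(clones, grid, p_tumor, umi_len)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list(
    r1 = file.path(out_dir, paste0("reads_R1", ext)),
    r2 = file.path(out_dir, paste0("reads_R2", ext)),
    whitelist = file.path(out_dir, "whitelist.txt"),
    positions = file.path(out_dir, "tissue_positions_list.csv"),
    regions = file.path(out_dir, "regions.csv"),
    clone_truth = file.path(out_dir, "clone_truth.tsv"),
    read_map = file.path(out_dir, "read_clone_map.tsv"),
    cells = file.path(out_dir, "cells.csv"),
    cefx_pos = file.path(out_dir, "cefx_ifng_pos.tsv"),
    cefx_neg = file.path(out_dir, "cefx_ifng_neg.tsv"),
    config = file.path(out_dir, "config_echo.yaml"))
  truth_map <- emit_fastq(placed$placements, clones, refs,
                          paths$r1, paths$r2, reads_per_umi,
                          err_barcode, err_umi, err_insert)
  cells <- simulate_cell_table(clones, cells_per_clone, purity)
  cefx <- simulate_cefx_tables(clones, n_specific)

  writeLines(grid$barcode, paths$whitelist)
  utils::write.table(attr(grid, "positions"), paths$positions, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(attr(grid, "regions"), paths$regions, row.names = FALSE,
                   quote = FALSE)
  utils::write.table(clones, paths$clone_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth_map[, c("read_id", "clone_id")], paths$read_map,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cells, paths$cells, row.names = FALSE, quote = FALSE)
  write_adaptive_tsv <- function(rep, path) {
    key <- parse_clone_id(names(rep$counts))
    utils::write.table(
      data.frame(amino_acid = key$cdr3_aa, v_family = key$v_family,
                 j_family = key$j_family, templates = unname(rep$counts)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_adaptive_tsv(cefx$pos, paths$cefx_pos)
  write_adaptive_tsv(cefx$neg, paths$cefx_neg)
  cfg <- list(seed = seed, n_rows = n_rows, n_cols = n_cols,
              tumor_radius_um = tumor_radius_um, pitch_um = pitch_um,
              n_clones = n_clones, zipf_exponent = zipf_exponent,
              total_umis = total_umis, umis_per_clone = umis_per_clone,
              p_ad = p_ad, p_tumor = as.list(p_tumor),
              reads_per_umi = reads_per_umi, err_barcode = err_barcode,
              err_umi = err_umi, err_insert = err_insert,
              barcode_len = barcode_len, umi_len = umi_len)
  yaml::write_yaml(cfg, paths$config)
  invisible(list(grid = grid, clones = clones,
                 placements = placed$placements, counts = placed$counts,
                 truth_map = truth_map, cells = cells, cefx = cefx,
                 paths = paths, config = cfg))
}
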