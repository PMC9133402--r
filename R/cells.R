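#' Assemble a cell table
#'
#' One row per cell barcode with its resolved TCRbeta clonotype (if any),
#' metacluster label, patient, and compartment. The alpha chains of each cell
#' live in a separate long table (see [rescue_beta_by_alpha()]).
#'
#' @param cell_id Character vector of cell barcodes.
#' @param clone_id TCRbeta clone identifier per cell (`NA` if undetermined).
#' @param metacluster One of `"A"`, `"B"`, `"C"`, `"D"`, `"naive"`,
#'   `"unassigned"`.
#' @param patient,compartment Character labels; compartment is `"tumor"` or
#'   `"blood"`.
#' @return data.frame with an additional `beta_source` column
#'   (`"direct"` where a beta chain was observed, `NA` otherwise).
#' @export
cell_table <- function(cell_id, clone_id = NA_character_,
                       metacluster = "unassigned",
                       patient = "p1", compartment = "tumor") {
  metacluster <- as.character(metacluster)
  bad <- !metacluster %in% c("A", "B", "C", "D", "naive", "unassigned")
  if (any(bad)) stop("unknown metacluster label: ",
                     paste(unique(metacluster[bad]), collapse = ", "))
  compartment <- as.character(compartment)
  if (!all(compartment %in% c("tumor", "blood")))
    stop("compartment must be 'tumor' or 'blood'")
  df <- data.frame(cell_id = as.character(cell_id),
                   clone_id = as.character(clone_id),
                   metacluster = metacluster,
                   patient = as.character(patient),
                   compartment = compartment,
                   stringsAsFactors = FALSE)
  df$beta_source <- ifelse(is.na(df$clone_id), NA_character_, "direct")
  df
}

#' Rescue undetermined beta clonotypes through shared alpha chains
#'
#' A cell with no determined TCRbeta but at least one TCRalpha is assigned to
#' clone K if and only if every other cell carrying that alpha chain and
#' having a determined beta maps to K, and at least one such cell exists.
#' Alpha identity is the exact (V gene, J gene, CDR3 nucleotide) triple --
#' stricter than the family-level beta clone identity -- to minimize false
#' rescue. When a cell carries several alpha chains, the beta evidence pooled
#' across them must still name a single clone.
#'
#' Only directly observed beta chains (`beta_source == "direct"`) provide
#' evidence, so the operation is idempotent: rescued cells never propagate
#' assignments to further cells.
#'
#' @param cells Cell table as built by [cell_table()].
#' @param alphas data.frame with columns `cell_id`, `v_gene`, `j_gene`,
#'   `cdr3_nt` (one row per alpha chain).
#' @return `cells` with rescued rows filled in (`beta_source =
#'   "alpha_rescue"`).
#' @export
rescue_beta_by_alpha <- function(cells, alphas) {
  if (nrow(cells) == 0L || is.null(alphas) || nrow(alphas) == 0L)
    return(cells)
  akey <- paste(alphas$v_gene, alphas$j_gene, alphas$cdr3_nt, sep = "|")
  determined <- cells$cell_id[!is.na(cells$clone_id) &
                                cells$beta_source %in% "direct"]
  clone_of <- cells$clone_id[match(alphas$cell_id, cells$cell_id)]
  is_evidence <- alphas$cell_id %in% determined
  # per alpha key, the set of beta clones seen among determined cells
  ev <- split(clone_of[is_evidence], akey[is_evidence])
  candidates <- which(is.na(cells$clone_id))
  for (i in candidates) {
    keys <- unique(akey[alphas$cell_id == cells$cell_id[i]])
    if (length(keys) == 0L) next
    support <- unlist(lapply(keys, function(k) {
      v <- ev[[k]]
      # evidence from *other* cells only (a cell cannot vouch for itself,
      # though an undetermined cell has no direct beta to contribute anyway)
      unique(v)
    }))
    support <- unique(support)
    if (length(support) == 1L) {
      cells$clone_id[i] <- support
      cells$beta_source[i] <- "alpha_rescue"
    }
  }
  cells
}

#' Classify clone phenotype from single-cell metacluster membership
#'
#' Each clone is called an A/D (terminally differentiated / dividing) or B/C
#' (progenitor- / memory-like) clone by strict majority of its cells among
#' metaclusters A--D; naive and unassigned cells are ignored. Ties with at
#' least one counted cell are `"ambiguous"`; clones with no counted cells
#' are `"unclassified"`.
#'
#' @param cells Cell table with resolved `clone_id` (after rescue).
#' @param clone_id Optional character vector restricting/ordering the output;
#'   defaults to all clones present in `cells`.
#' @return data.frame with one row per clone: per-metacluster cell counts
#'   `n_A` .. `n_D` and the `call`.
#' @export
classify_clone_phenotype <- function(cells, clone_id = NULL) {
  counted <- cells[!is.na(cells$clone_id) &
                     cells$metacluster %in% c("A", "B", "C", "D"), ,
                   drop = FALSE]
  if (is.null(clone_id))
    clone_id <- sort(unique(cells$clone_id[!is.na(cells$clone_id)]))
  tab <- table(factor(counted$clone_id, levels = clone_id),
               factor(counted$metacluster, levels = c("A", "B", "C", "D")))
  n <- as.data.frame.matrix(tab)
  names(n) <- paste0("n_", names(n))
  ad <- n$n_A + n$n_D
  bc <- n$n_B + n$n_C
  call <- ifelse(ad + bc == 0L, "unclassified",
                 ifelse(ad > bc, "AD", ifelse(bc > ad, "BC", "ambiguous")))
  data.frame(clone_id = clone_id, n, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of cells carrying antigen-specific clonotypes
#'
#' @param clone_id Resolved clone assignment per cell of one population.
#' @param specific Character vector (or set) of specific clone ids, e.g. the
#'   output of [cefx_specific_clones()].
#' @return Percentage (0--100) of cells whose clone is in `specific`; cells
#'   without a resolved clone count toward the denominator.
#' @export
bystander_fraction <- function(clone_id, specific) {
  if (length(clone_id) == 0L) stop("empty population")
  100 * mean(clone_id %in% specific)
}

#' Look up paired-chain TCRs in a known-specificity database
#'
#' A cell matches a database record iff all six fields agree exactly:
#' CDR3alpha, CDR3beta amino-acid sequences and the TRAV, TRAJ, TRBV, TRBJ
#' gene names (gene-level, not family-level). Cells lacking either chain
#' match nothing.
#'
#' @param cells data.frame with one row per cell and columns `cdr3_alpha`,
#'   `cdr3_beta`, `trav`, `traj`, `trbv`, `trbj` (NA where a chain is
#'   missing).
#' @param db data.frame with the same six columns plus annotation columns
#'   such as `antigen_epitope` and `antigen_species` (see
#'   [read_vdjdb_tsv()]).
#' @return data.frame of (cell row, db row) matches with db annotations.
#' @export
vdjdb_lookup <- function(cells, db) {
  need <- c("cdr3_alpha", "cdr3_beta", "trav", "traj", "trbv", "trbj")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells table lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need, names(db))
  if (length(miss)) stop("db table lacks column(s): ",
                         paste(miss, collapse = ", "))
  keyify <- function(d) {
    complete <- !Reduce(`|`, lapply(d[need], is.na))
    k <- do.call(paste, c(d[need], sep = "\r"))
    k[!complete] <- NA_character_
    k
  }
  ck <- keyify(cells)
  dk <- keyify(db)
  hits <- which(!is.na(ck) & ck %in% dk)
  out <- do.call(rbind, lapply(hits, function(i) {
    j <- which(dk == ck[i])
    cbind(cell_row = i, db[j, , drop = FALSE], row.names = NULL)
  }))
  if (is.null(out))
    out <- cbind(cell_row = integer(0), db[0, , drop = FALSE])
  out
}
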