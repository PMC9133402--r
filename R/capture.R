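#' Read a FASTQ file into a data.frame of ids and sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; handles gzipped input
#' and strips mate (`/1`, `/2`) and whitespace suffixes from read ids so they
#' match external clone-caller exports.
#'
#' @param path FASTQ(.gz) path.
#' @return data.frame with `read_id` and `seq`.
#' @export
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = strip_read_id(names(x)),
             seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Canonicalize read identifiers
#'
#' @param ids Character vector of FASTQ headers or export read names.
#' @return Ids with everything after the first whitespace, and any trailing
#'   `/1` or `/2` mate suffix, removed.
#' @export
strip_read_id <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Split read 1 into spot barcode and UMI
#'
#' @param seq Character vector of read-1 sequences.
#' @param barcode_len,umi_len Segment lengths (Visium v1: 16 + 12); trailing
#'   bases are ignored.
#' @return data.frame with `barcode`, `umi` (NA where the read is shorter
#'   than `barcode_len + umi_len`) and logical `too_short`.
#' @export
parse_read1 <- function(seq, barcode_len = 16L, umi_len = 12L) {
  need <- barcode_len + umi_len
  too_short <- nchar(seq) < need
  barcode <- ifelse(too_short, NA_character_, substr(seq, 1L, barcode_len))
  umi <- ifelse(too_short, NA_character_,
                substr(seq, barcode_len + 1L, need))
  data.frame(barcode = barcode, umi = umi, too_short = too_short,
             stringsAsFactors = FALSE)
}

#' Build a barcode whitelist with a precomputed one-mismatch index
#'
#' The index maps every sequence at Hamming distance exactly 1 from a unique
#' whitelist entry (substitutions over A/C/G/T/N; `N` mismatches every base)
#' back to that entry. Sequences within distance 1 of two or more entries are
#' ambiguous and excluded.
#'
#' @param barcodes Character vector of equal-length barcodes, or a path to a
#'   one-barcode-per-line text file.
#' @return Object of class `"barcode_whitelist"`.
#' @export
barcode_whitelist <- function(barcodes) {
  if (length(barcodes) == 1L && file.exists(barcodes))
    barcodes <- readLines(barcodes)
  barcodes <- barcodes[nzchar(barcodes)]
  len <- unique(nchar(barcodes))
  if (length(len) != 1L) stop("whitelist barcodes must share one length")
  if (anyDuplicated(barcodes)) stop("whitelist barcodes must be unique")
  alphabet <- c("A", "C", "G", "T", "N")
  nb <- vector("list", len * length(alphabet))
  k <- 0L
  for (pos in seq_len(len)) {
    orig <- substr(barcodes, pos, pos)
    for (sub in alphabet) {
      k <- k + 1L
      mut <- barcodes
      substr(mut, pos, pos) <- sub
      keep <- orig != sub
      nb[[k]] <- data.frame(neighbor = mut[keep], entry = barcodes[keep],
                            stringsAsFactors = FALSE)
    }
  }
  nb <- unique(do.call(rbind, nb))
  # drop neighbors that are themselves entries (exact match wins) and
  # neighbors claimed by more than one entry (ambiguous)
  nb <- nb[!nb$neighbor %in% barcodes, , drop = FALSE]
  dup <- nb$neighbor %in% nb$neighbor[duplicated(nb$neighbor)]
  nb <- nb[!dup, , drop = FALSE]
  structure(list(barcodes = barcodes, barcode_len = len,
                 neighbor = nb$neighbor, neighbor_entry = nb$entry),
            class = "barcode_whitelist")
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf("barcode whitelist: %d barcodes of length %d\n",
              length(x$barcodes), x$barcode_len))
  invisible(x)
}

#' Correct observed barcodes against a whitelist
#'
#' Exact members map to themselves; otherwise a barcode with exactly one
#' whitelist entry at Hamming distance 1 maps to that entry; anything else
#' (including ties and wrong lengths) is unassigned.
#'
#' @param observed Character vector of observed barcodes.
#' @param whitelist A [barcode_whitelist()].
#' @return Character vector of corrected barcodes, `NA` where unassigned;
#'   attribute `"reason"` distinguishes `"barcode_length"` from
#'   `"barcode_unassigned"`.
#' @export
correct_barcode <- function(observed, whitelist) {
  stopifnot(inherits(whitelist, "barcode_whitelist"))
  out <- rep(NA_character_, length(observed))
  reason <- rep(NA_character_, length(observed))
  bad_len <- is.na(observed) | nchar(observed) != whitelist$barcode_len
  reason[bad_len] <- "barcode_length"
  exact <- !bad_len & observed %in% whitelist$barcodes
  out[exact] <- observed[exact]
  rest <- which(!bad_len & !exact)
  hit <- match(observed[rest], whitelist$neighbor)
  out[rest] <- whitelist$neighbor_entry[hit]
  reason[rest[is.na(hit)]] <- "barcode_unassigned"
  attr(out, "reason") <- reason
  out
}

#' Load a clone-to-supporting-read export
#'
#' Consumes tab-separated exports in the style of an external clone caller's
#' per-clone read listing (one row per supporting read). Duplicate read ids
#' naming conflicting clones are dropped entirely and counted.
#'
#' @param path TSV path with a header.
#' @param read_col,clone_col Column names holding the read and clone
#'   identifiers.
#' @return Named character vector `read_id -> clone_id`; attribute
#'   `"n_conflicts"` counts reads dropped for conflicting assignments.
#' @export
load_clone_read_map <- function(path, read_col = "read_id",
                                clone_col = "clone_id") {
  df <- read_delim_checked(path, list(read_col, clone_col), sep = "\t",
                           what = "clone read map")
  ids <- strip_read_id(as.character(df[[read_col]]))
  clones <- as.character(df[[clone_col]])
  dt <- unique(data.table::data.table(read_id = ids, clone_id = clones))
  n_per_read <- dt[, .N, by = "read_id"]
  conflicted <- n_per_read$read_id[n_per_read$N > 1L]
  dt <- dt[!dt$read_id %in% conflicted, ]
  out <- stats::setNames(dt$clone_id, dt$read_id)
  attr(out, "n_conflicts") <- length(conflicted)
  out
}

#' Build the deduplicated clone-by-spot UMI matrix
#'
#' For every read with a clone assignment and a whitelist-corrected spot
#' barcode, the triple (clone, spot, UMI) is recorded; the UMI count of a
#' (clone, spot) cell is the number of *distinct* UMI sequences observed
#' there, so PCR duplicates (identical triples) collapse to one molecule.
#' The QC report counts every read by fate.
#'
#' @param r1 Read-1 input: a FASTQ(.gz) path or a data.frame with `read_id`
#'   and `seq` columns (see [read_fastq_seqs()]).
#' @param clone_map Named vector `read_id -> clone_id`
#'   ([load_clone_read_map()] or the read map of [call_clones_from_fastq()]).
#' @param whitelist A [barcode_whitelist()].
#' @param barcode_len,umi_len Read-1 structure.
#' @param clone_table Optional clone annotation table carried through to the
#'   result.
#' @param grid Optional [build_spot_grid()]; when given, an `in_tissue` flag
#'   is attached to each matrix row (out-of-tissue spots are retained but
#'   flagged).
#' @return list of class `"spatial_clone_matrix"`: `counts` (data.frame
#'   `clone_id`, `barcode`, `umi_count`), `clone_table`, and `qc` (named
#'   read-fate counts: assigned, no_clone, barcode_unassigned,
#'   barcode_length, too_short).
#' @export
build_spatial_clone_matrix <- function(r1, clone_map, whitelist,
                                       barcode_len = 16L, umi_len = 12L,
                                       clone_table = NULL, grid = NULL) {
  if (is.character(r1) && length(r1) == 1L) r1 <- read_fastq_seqs(r1)
  stopifnot(all(c("read_id", "seq") %in% names(r1)))
  parsed <- parse_read1(r1$seq, barcode_len, umi_len)
  clone <- unname(clone_map[strip_read_id(r1$read_id)])
  corrected <- correct_barcode(parsed$barcode, whitelist)
  reason <- attr(corrected, "reason")

  fate <- rep("assigned", nrow(r1))
  fate[is.na(corrected)] <- reason[is.na(corrected)]
  fate[parsed$too_short] <- "too_short"
  fate[!parsed$too_short & !is.na(corrected) & is.na(clone)] <- "no_clone"
  ok <- fate == "assigned"

  dt <- data.table::data.table(clone_id = clone[ok],
                               barcode = corrected[ok],
                               umi = parsed$umi[ok])
  dt <- unique(dt)
  counts <- dt[, list(umi_count = .N), by = c("clone_id", "barcode")]
  data.table::setorder(counts, clone_id, barcode)
  counts <- as.data.frame(counts)
  if (!is.null(grid))
    counts$in_tissue <- grid$in_tissue[match(counts$barcode, grid$barcode)]
  qc <- c(assigned = sum(fate == "assigned"),
          no_clone = sum(fate == "no_clone"),
          barcode_unassigned = sum(fate == "barcode_unassigned"),
          barcode_length = sum(fate == "barcode_length"),
          too_short = sum(fate == "too_short"))
  structure(list(counts = counts, clone_table = clone_table, qc = qc),
            class = "spatial_clone_matrix")
}

#' @export
print.spatial_clone_matrix <- function(x, ...) {
  cat(sprintf(
    "spatial clone matrix: %d clones x %d spots, %d UMIs (%d/%d reads assigned)\n",
    length(unique(x$counts$clone_id)), length(unique(x$counts$barcode)),
    sum(x$counts$umi_count), x$qc[["assigned"]], sum(x$qc)))
  invisible(x)
}
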