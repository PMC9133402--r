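#' Toy V/J segment reference bundled for testing and simulation
#'
#' Six TRBV and four TRBJ synthetic germline segments with valid CDR3
#' anchors: every V ends in a conserved-cysteine codon (`TGT`, anchor at the
#' last codon) and every J begins with the phenylalanine codon (`TTC`) of the
#' FGxG motif. Sequences are fixed arbitrary nucleotides sharing no 12-mer
#' across distinct segments, so seed-and-extend assignment is unambiguous.
#' They are synthetic stand-ins, not IMGT germline sequences.
#'
#' @return data.frame (`segment_reference`): `name`, `chain`, `seq`,
#'   `anchor_start` (1-based offset of the conserved-residue codon).
#' @export
toy_segment_reference <- function() {
  v <- c(
    "TRBV6-2"  = "GTTTGTAGACGTATATTATTCATTTCCTATTGCATCAGGGAGCCCAGAATTGGAAAGTGT",
    "TRBV6-3"  = "ACTTCTTCTCACCTTGTAATAAAATAATTAGCGATTGACTATCATAGTCGAGTTGTATGT",
    "TRBV9"    = "GCCAAAAATGAAGGCCGAACTTGGTTTGGTCCAACTGTGACGTTACAAGGAGCAGTCTGT",
    "TRBV19"   = "TGTGCCGATATGCCAAGTCTAATGATTTGATTCCGACCGAGGGAAAGAGAGATTTGATGT",
    "TRBV20-1" = "TACCCGATTGCCTGCTTCGCCGACCCGAGTAGAAACTGGGGATTCGGTCCGTGTCAATGT",
    "TRBV28"   = "ATTGATCTTATCGGTAGCTTCTTAGGCGCGTGCAAGACCGTCCCACCATTTAAATTGTGT")
  j <- c(
    "TRBJ1-1" = "TTCAGTCAGTTGCGCAAGCTTCGGTACATCGAAGATTACCTAGTCGTG",
    "TRBJ1-2" = "TTCAGTCTTGGTGGCGCTCAAGTAGAACACATCTACTAAATAATCGTA",
    "TRBJ2-1" = "TTCCCACCCGTAGCGTACGTTGCATCGATTGACGGAGATACTGTTCCT",
    "TRBJ2-7" = "TTCAGCTGTCTTGTTCCTAGCTCCCACGTTTGACAATTCGAACGGCCA")
  rbind(
    data.frame(name = names(v), chain = "TRB", seq = unname(v),
               anchor_start = nchar(unname(v)) - 2L,
               type = "V", stringsAsFactors = FALSE),
    data.frame(name = names(j), chain = "TRB", seq = unname(j),
               anchor_start = 1L, type = "J", stringsAsFactors = FALSE))
}

#' Read a segment reference from FASTA plus anchor sidecar
#'
#' @param fasta FASTA of germline segment sequences (names = segment names;
#'   V segments contain `V`, J segments `J`).
#' @param anchors TSV with columns `name` and `anchor_start` (1-based start
#'   of the conserved Cys codon for V, of the FGxG Phe codon for J).
#' @return `segment_reference` data.frame as in [toy_segment_reference()].
#' @export
read_segment_reference <- function(fasta, anchors) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  a <- read_delim_checked(anchors, list("name", "anchor_start"), sep = "\t",
                          what = "anchor sidecar")
  nm <- sub("\\s.*$", "", names(seqs))
  idx <- match(nm, a$name)
  if (anyNA(idx)) stop("anchor sidecar lacks segment(s): ",
                       paste(nm[is.na(idx)], collapse = ", "))
  fam <- normalize_gene_family(nm)   # validates the names
  data.frame(name = nm, chain = substr(fam, 1, 3), seq = as.character(seqs),
             anchor_start = as.integer(a$anchor_start[idx]),
             type = substr(fam, 4, 4), stringsAsFactors = FALSE)
}

seg_kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmers = character(0), pos = integer(0)))
  pos <- seq_len(n - k + 1L)
  list(kmers = substring(seq, pos, pos + k - 1L), pos = pos)
}

max_subarray <- function(v) {
  # Kadane with start tracking; returns (score, start, end); all-negative
  # input yields the single best element.
  best <- -Inf; best_s <- 1L; best_e <- 1L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(v)) {
    if (cur <= 0) { cur <- v[i]; cur_s <- i } else cur <- cur + v[i]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
  }
  c(score = best, start = best_s, end = best_e)
}

#' Ungapped seed-and-extend alignment of a read against one segment
#'
#' Shared k-mers between read and reference define candidate diagonals; on
#' each diagonal the best-scoring contiguous ungapped segment (match +1,
#' mismatch -1) is found, and the best over all seeded diagonals is
#' returned. No indels are considered.
#'
#' @param read Nucleotide string.
#' @param ref_seq Reference segment sequence.
#' @param k Seed length (>= 8).
#' @return `NULL` if no shared k-mer; otherwise list with `score`,
#'   `read_start`, `ref_start` (1-based starts of the best segment) and
#'   `diag = read_start - ref_start`.
#' @export
align_segment <- function(read, ref_seq, k = 12L) {
  if (k < 8L) stop("seed length k must be >= 8")
  nr <- nchar(read); nf <- nchar(ref_seq)
  if (nr < k || nf < k) return(NULL)
  ri <- seg_kmer_index(read, k)
  fi <- seg_kmer_index(ref_seq, k)
  hits <- match(ri$kmers, fi$kmers)
  seeded <- which(!is.na(hits))
  if (length(seeded) == 0L) return(NULL)
  # a k-mer may occur several times in the reference; enumerate all
  diags <- integer(0)
  for (s in seeded) {
    fpos <- fi$pos[which(fi$kmers == ri$kmers[s])]
    diags <- c(diags, ri$pos[s] - fpos)
  }
  diags <- sort(unique(diags))
  read_chars <- strsplit(read, "", fixed = TRUE)[[1]]
  ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  best <- NULL
  for (d in diags) {
    rs <- max(1L, 1L + d); re <- min(nr, nf + d)
    if (re < rs) next
    seg <- ifelse(read_chars[rs:re] == ref_chars[(rs - d):(re - d)], 1, -1)
    m <- max_subarray(seg)
    cand <- list(score = unname(m["score"]),
                 read_start = rs + unname(m["start"]) - 1L,
                 ref_start = rs + unname(m["start"]) - 1L - d,
                 diag = d)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$ref_start < best$ref_start))
      best <- cand
  }
  best
}

#' Assign the best V and J segment to a read
#'
#' @param read Nucleotide string (read 2 of the targeted TCR library).
#' @param refs `segment_reference` data.frame.
#' @param k Seed length.
#' @return `NULL` if either the V or the J side has no seeded hit; otherwise
#'   list with `v` and `j`, each holding `name` and the [align_segment()]
#'   result. Score ties break lexicographically on the segment name.
#' @export
call_vj <- function(read, refs, k = 12L) {
  pick <- function(type) {
    sub <- refs[refs$type == type, , drop = FALSE]
    sub <- sub[order(sub$name), , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(sub))) {
      al <- align_segment(read, sub$seq[i], k)
      if (is.null(al)) next
      if (is.null(best) || al$score > best$al$score)
        best <- list(name = sub$name[i], anchor_start = sub$anchor_start[i],
                     al = al)
    }
    best
  }
  v <- pick("V"); j <- pick("J")
  if (is.null(v) || is.null(j)) return(NULL)
  list(v = v, j = j)
}

#' Extract the CDR3 between the V and J anchors
#'
#' The CDR3 spans from the start of the conserved V cysteine codon to the
#' end of the J FGxG phenylalanine codon, inclusive (both anchor residues
#' included), located in the read through the alignment diagonals.
#'
#' @param read Nucleotide string.
#' @param vj Result of [call_vj()].
#' @return `NULL` when an anchor falls outside the read or the J anchor
#'   precedes the V anchor; otherwise list with `cdr3_nt`, `cdr3_aa`
#'   (translated; `NA` when the length is not a multiple of 3) and
#'   `productive` (in-frame, no stop, no ambiguous codon).
#' @export
extract_cdr3 <- function(read, vj) {
  v_start <- vj$v$anchor_start + vj$v$al$diag
  j_end <- vj$j$anchor_start + vj$j$al$diag + 2L
  n <- nchar(read)
  if (v_start < 1L || j_end > n || j_end < v_start) return(NULL)
  cdr3_nt <- substr(read, v_start, j_end)
  len <- nchar(cdr3_nt)
  if (len %% 3L != 0L)
    return(list(cdr3_nt = cdr3_nt, cdr3_aa = NA_character_,
                productive = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cdr3_nt), if.fuzzy.codon = "X"))
  list(cdr3_nt = cdr3_nt, cdr3_aa = aa,
       productive = !grepl("[*X]", aa))
}

#' Call clonotypes from read-2 sequences
#'
#' Annotates each read with its best V/J segments and extracted CDR3, keeps
#' productive annotations, and groups them into family-level clonotypes via
#' [build_clone_key()]. Identical read sequences are annotated once.
#'
#' @param r2 FASTQ(.gz) path or data.frame with `read_id`, `seq`.
#' @param refs `segment_reference` data.frame.
#' @param k Seed length.
#' @return list with `clone_table` (data.frame `clone_id`, `v_gene`,
#'   `j_gene`, `cdr3_nt`, `cdr3_aa`, `read_count`), `read_map` (named vector
#'   `read_id -> clone_id`), and `qc` (reads by fate: assigned, no_vj,
#'   unproductive, anchor_outside).
#' @export
call_clones_from_fastq <- function(r2, refs, k = 12L) {
  if (is.character(r2) && length(r2) == 1L) r2 <- read_fastq_seqs(r2)
  empty <- list(
    clone_table = data.frame(clone_id = character(0), v_gene = character(0),
                             j_gene = character(0), cdr3_nt = character(0),
                             cdr3_aa = character(0), read_count = integer(0)),
    read_map = stats::setNames(character(0), character(0)),
    qc = c(assigned = 0L, no_vj = 0L, unproductive = 0L, anchor_outside = 0L))
  if (nrow(r2) == 0L) return(empty)
  uniq <- unique(r2$seq)
  ann <- lapply(uniq, function(s) {
    vj <- call_vj(s, refs, k)
    if (is.null(vj)) return(list(fate = "no_vj"))
    cd <- extract_cdr3(s, vj)
    if (is.null(cd)) return(list(fate = "anchor_outside"))
    if (!cd$productive) return(list(fate = "unproductive"))
    list(fate = "assigned", v = vj$v$name, j = vj$j$name,
         cdr3_nt = cd$cdr3_nt, cdr3_aa = cd$cdr3_aa)
  })
  fate_u <- vapply(ann, `[[`, "", "fate")
  idx <- match(r2$seq, uniq)
  fate <- fate_u[idx]
  qc <- c(assigned = sum(fate == "assigned"),
          no_vj = sum(fate == "no_vj"),
          unproductive = sum(fate == "unproductive"),
          anchor_outside = sum(fate == "anchor_outside"))
  ok_u <- which(fate_u == "assigned")
  if (length(ok_u) == 0L) { empty$qc <- qc; return(empty) }
  vg <- vapply(ann[ok_u], `[[`, "", "v")
  jg <- vapply(ann[ok_u], `[[`, "", "j")
  nt <- vapply(ann[ok_u], `[[`, "", "cdr3_nt")
  aa <- vapply(ann[ok_u], `[[`, "", "cdr3_aa")
  keys <- build_clone_key(vg, jg, aa)
  clone_of_uniq <- rep(NA_character_, length(uniq))
  clone_of_uniq[ok_u] <- keys$clone_id
  per_read_clone <- clone_of_uniq[idx]
  keep <- !is.na(per_read_clone)
  read_map <- stats::setNames(per_read_clone[keep],
                              strip_read_id(r2$read_id)[keep])
  ct <- data.frame(clone_id = keys$clone_id, v_gene = vg, j_gene = jg,
                   cdr3_nt = nt, cdr3_aa = aa,
                   n_reads_uniq = as.integer(table(r2$seq)[uniq[ok_u]]),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(n_reads_uniq ~ clone_id, data = ct, FUN = sum)
  first <- ct[!duplicated(ct$clone_id), c("clone_id", "v_gene", "j_gene",
                                          "cdr3_nt", "cdr3_aa")]
  clone_table <- merge(first, agg, by = "clone_id", sort = TRUE)
  names(clone_table)[names(clone_table) == "n_reads_uniq"] <- "read_count"
  list(clone_table = clone_table, read_map = read_map, qc = qc)
}

#' Write lite-caller outputs in external-export-compatible form
#'
#' @param calls Result of [call_clones_from_fastq()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths (clone table TSV and read-map TSV
#'   readable by [load_clone_read_map()]).
#' @export
write_clone_calls <- function(calls, dir, prefix = "clones") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_table.tsv"))
  utils::write.table(calls$clone_table, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_reads.tsv"))
  utils::write.table(
    data.frame(read_id = names(calls$read_map),
               clone_id = unname(calls$read_map)),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
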