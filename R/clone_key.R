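#' Normalize a V/J segment name to its gene family
#'
#' Clonotype identity is defined at the level of gene *families*: the IMGT
#' segment name is stripped of any allele suffix (`*01`) and truncated at the
#' first hyphen, so `TRBV6-2*01` and `TRBV6-3` both normalize to `TRBV6`.
#' Multi-gene annotations (`TRBV20-1/TRBV20OR9-2`) use the first listed gene.
#'
#' @param gene Character vector of IMGT-style segment names.
#' @return Character vector of family names.
#' @examples
#' normalize_gene_family(c("TRBV6-2*01", "TRBJ2-7", "TRBV20-1/TRBV20OR9-2"))
#' @export
normalize_gene_family <- function(gene) {
  if (length(gene) == 0L) return(character(0))
  if (!is.character(gene)) stop("`gene` must be a character vector")
  if (any(is.na(gene) | !nzchar(gene)))
    stop("invalid gene name: empty or NA segment name")
  fam <- sub("/.*$", "", gene)        # first listed gene of multi-gene calls
  fam <- sub("\\*.*$", "", fam)       # drop allele suffix
  fam <- sub("-.*$", "", fam)         # truncate at family boundary
  bad <- !grepl("^TR[AB][VJ]", fam)
  if (any(bad))
    stop("invalid gene name (no TRAV/TRAJ/TRBV/TRBJ prefix): ",
         paste(unique(gene[bad]), collapse = ", "))
  fam
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_productive_cdr3 <- function(cdr3_aa) {
  !is.na(cdr3_aa) & nzchar(cdr3_aa) &
    !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), cdr3_aa)
}

#' Build TCRbeta clonotype keys
#'
#' A clonotype is identified by the triple (TRBV family, TRBJ family, CDR3
#' amino-acid sequence); records agreeing on all three are the same clone.
#' Non-productive CDR3s (stop `*`, frameshift `_`, or any character outside
#' the 20-letter amino-acid alphabet) are rejected, reported via the
#' `"rejected"` attribute, and never become clonotypes.
#'
#' @param v_call,j_call Character vectors of TRB V/J segment names.
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences (uppercase).
#' @return A data.frame with columns `v_family`, `j_family`, `cdr3_aa` and a
#'   combined `clone_id` string; rejected records (with a `reason` column)
#'   are attached as attribute `"rejected"`.
#' @examples
#' build_clone_key("TRBV6-2*01", "TRBJ2-7", "CASSLGQAYEQYF")
#' @export
build_clone_key <- function(v_call, j_call, cdr3_aa) {
  n <- length(cdr3_aa)
  stopifnot(length(v_call) == n, length(j_call) == n)
  v_family <- normalize_gene_family(v_call)
  j_family <- normalize_gene_family(j_call)
  bad_chain <- !startsWith(v_family, "TRBV") | !startsWith(j_family, "TRBJ")
  if (any(bad_chain))
    stop("clone keys are TCRbeta-only: V must be TRBV and J must be TRBJ")
  ok <- is_productive_cdr3(cdr3_aa)
  keys <- data.frame(
    v_family = v_family[ok], j_family = j_family[ok], cdr3_aa = cdr3_aa[ok],
    stringsAsFactors = FALSE
  )
  keys$clone_id <- clone_id_string(keys$v_family, keys$j_family, keys$cdr3_aa)
  attr(keys, "rejected") <- data.frame(
    v_call = v_call[!ok], j_call = j_call[!ok], cdr3_aa = cdr3_aa[!ok],
    reason = rep("non_productive_cdr3", sum(!ok)), stringsAsFactors = FALSE
  )
  keys
}

#' Combined clone identifier string
#'
#' @param v_family,j_family,cdr3_aa Clone key fields.
#' @return `"<v_family>_<j_family>_<cdr3_aa>"`; equal strings iff equal keys.
#' @export
clone_id_string <- function(v_family, j_family, cdr3_aa) {
  paste(v_family, j_family, cdr3_aa, sep = "_")
}

#' Split clone identifier strings back into key fields
#'
#' @param clone_id Character vector produced by [clone_id_string()].
#' @return data.frame with `v_family`, `j_family`, `cdr3_aa`, `clone_id`.
#' @export
parse_clone_id <- function(clone_id) {
  parts <- strsplit(clone_id, "_", fixed = TRUE)
  stopifnot(all(lengths(parts) == 3L))
  data.frame(
    v_family = vapply(parts, `[`, "", 1L),
    j_family = vapply(parts, `[`, "", 2L),
    cdr3_aa  = vapply(parts, `[`, "", 3L),
    clone_id = clone_id, stringsAsFactors = FALSE
  )
}
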