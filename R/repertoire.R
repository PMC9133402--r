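#' Construct a repertoire of clone counts
#'
#' @param counts Named numeric vector of positive integer counts (cells or
#'   templates), names are clone ids.
#' @param label Free-text label of the population (e.g. `"PD-1+ blood"`).
#' @return An object of class `"repertoire"`: list with `counts`, `total`,
#'   `label`.
#' @export
repertoire <- function(counts, label = "") {
  counts <- counts[counts > 0]
  if (length(counts) && (is.null(names(counts)) || anyNA(names(counts))))
    stop("counts must be named by clone id")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  structure(list(counts = counts, total = sum(counts), label = label),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("repertoire '%s': %d clones, %d total counts\n",
              x$label, length(x$counts), x$total))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "repertoire")) x$counts else x
}

#' Aggregate weighted clone records into a repertoire
#'
#' @param clone_id Character vector of clone ids, one per record.
#' @param weight Positive integer weights (default 1 per record).
#' @param label Population label.
#' @return A [repertoire()] with per-clone summed weights.
#' @export
aggregate_repertoire <- function(clone_id, weight = rep(1L, length(clone_id)),
                                 label = "") {
  stopifnot(length(weight) == length(clone_id))
  if (length(clone_id) == 0L)
    return(repertoire(stats::setNames(numeric(0), character(0)), label))
  if (any(weight <= 0) || any(weight != round(weight)))
    stop("weights must be positive integers")
  s <- tapply(weight, clone_id, sum)
  repertoire(stats::setNames(as.numeric(s), names(s)), label)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with \eqn{p_i} the clone frequencies,
#' natural logarithm.
#'
#' @param rep A [repertoire()] or a (named) numeric count vector.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(rep) {
  x <- as_counts(rep)
  x <- x[x > 0]
  if (length(x) == 0L) stop("Shannon index undefined for empty repertoire")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Morisita-Horn overlap index
#'
#' \deqn{MH = \frac{2\sum_i x_i y_i}{(d_x + d_y)\,X\,Y}} with
#' \eqn{X=\sum x_i}, \eqn{Y=\sum y_i}, \eqn{d_x=\sum x_i^2/X^2},
#' \eqn{d_y=\sum y_i^2/Y^2}, taken over the union of clones (missing counts
#' are 0). Ranges from 0 (disjoint) to 1 (identical frequency vectors).
#'
#' @param x,y Repertoires or named count vectors.
#' @return Overlap in `[0, 1]`.
#' @export
morisita_horn <- function(x, y) {
  xc <- as_counts(x); yc <- as_counts(y)
  xc <- xc[xc > 0]; yc <- yc[yc > 0]
  if (length(xc) == 0L || length(yc) == 0L)
    stop("Morisita-Horn undefined for empty repertoire")
  keys <- union(names(xc), names(yc))
  xi <- stats::setNames(numeric(length(keys)), keys)
  yi <- xi
  xi[names(xc)] <- xc
  yi[names(yc)] <- yc
  X <- sum(xi); Y <- sum(yi)
  dx <- sum(xi^2) / X^2
  dy <- sum(yi^2) / Y^2
  mh <- 2 * sum(xi * yi) / ((dx + dy) * X * Y)
  min(max(mh, 0), 1)
}

#' Pairwise Morisita-Horn overlap matrix
#'
#' @param reps List of repertoires (named list names become dimnames).
#' @return Symmetric matrix of [morisita_horn()] values with unit diagonal;
#'   rows/columns of empty repertoires are `NA`.
#' @export
pairwise_overlap_matrix <- function(reps) {
  n <- length(reps)
  if (n < 2L) stop("need at least two repertoires")
  m <- diag(1, n)
  empty <- vapply(reps, function(r) sum(as_counts(r)) == 0, TRUE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      m[i, j] <- m[j, i] <-
        if (empty[i] || empty[j]) NA_real_
        else morisita_horn(reps[[i]], reps[[j]])
    }
  }
  m[empty, ] <- NA_real_
  m[, empty] <- NA_real_
  diag(m)[empty] <- NA_real_
  dimnames(m) <- list(names(reps), names(reps))
  m
}

#' Clone rank / cumulative-frequency table
#'
#' Clones sorted by descending count, ties broken lexicographically on the
#' clone id for determinism; cumulative frequency is nondecreasing and ends
#' at 1.
#'
#' @param rep A [repertoire()] or named count vector.
#' @return data.frame with `clone_id`, `rank`, `count`, `frequency`,
#'   `cumulative_frequency`.
#' @export
clone_rank_cumulative <- function(rep) {
  x <- as_counts(rep)
  x <- x[x > 0]
  if (length(x) == 0L)
    return(data.frame(clone_id = character(0), rank = integer(0),
                      count = numeric(0), frequency = numeric(0),
                      cumulative_frequency = numeric(0)))
  o <- order(-x, names(x))
  x <- x[o]
  f <- x / sum(x)
  data.frame(clone_id = names(x), rank = seq_along(x), count = as.numeric(x),
             frequency = as.numeric(f),
             cumulative_frequency = cumsum(as.numeric(f)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' CEFX-responsive (microbe-specific) clone filter
#'
#' A clone is called CEFX-specific if it is found at least twice in the
#' IFN-gamma-positive sorted population and its frequency there is at least
#' five-fold its frequency in the IFN-gamma-negative population. Clones
#' absent from the negative population satisfy the ratio clause whenever the
#' count clause holds.
#'
#' @param pos,neg Repertoires (or named count vectors) of the IFN-gamma
#'   positive / negative sorted TCRbeta counts.
#' @param min_count Minimum count in `pos` (default 2).
#' @param min_ratio Minimum frequency ratio pos/neg (default 5).
#' @return Character vector of specific clone ids (sorted).
#' @export
cefx_specific_clones <- function(pos, neg, min_count = 2, min_ratio = 5) {
  pc <- as_counts(pos); nc <- as_counts(neg)
  pc <- pc[pc > 0]; nc <- nc[nc > 0]
  if (length(pc) == 0L) return(character(0))
  ptot <- sum(pc)
  ntot <- sum(nc)
  fpos <- pc / ptot
  fneg <- if (ntot > 0) {
    v <- stats::setNames(numeric(length(pc)), names(pc))
    shared <- intersect(names(pc), names(nc))
    v[shared] <- nc[shared] / ntot
    v
  } else stats::setNames(numeric(length(pc)), names(pc))
  keep <- pc >= min_count & fpos >= min_ratio * fneg
  sort(names(pc)[keep])
}
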