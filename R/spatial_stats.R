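#' Distance from each spot to the tumor border
#'
#' Tumor spots are at distance 0; for every other spot the distance is the
#' minimum Euclidean distance from its center to any tumor spot's center
#' (micrometers). No polygonal boundary is computed: the "border" is
#' implicit in the nearest tumor-labeled spot.
#'
#' @param grid A [build_spot_grid()] with at least one `is_tumor` spot.
#' @param barcode Optional barcodes to evaluate (default: all grid spots).
#' @return Named numeric vector of distances (names = barcodes).
#' @export
distance_to_tumor_border <- function(grid, barcode = NULL) {
  tum <- grid[grid$is_tumor, , drop = FALSE]
  if (nrow(tum) == 0L) stop("grid contains no tumor spots")
  if (is.null(barcode)) barcode <- grid$barcode
  idx <- match(barcode, grid$barcode)
  if (anyNA(idx)) stop("unknown spot barcode(s)")
  dx <- outer(grid$x[idx], tum$x, "-")
  dy <- outer(grid$y[idx], tum$y, "-")
  d <- sqrt(dx^2 + dy^2)
  out <- apply(d, 1L, min)
  out[grid$is_tumor[idx]] <- 0
  stats::setNames(out, barcode)
}

#' Percentage of a clone's UMIs found in the tumor parenchyma
#'
#' Only in-tissue spots are counted.
#'
#' @param clone_id Clone identifier.
#' @param mat [build_spatial_clone_matrix()] result (or its `counts`
#'   data.frame).
#' @param grid Spot grid.
#' @return Percentage in `[0, 100]`, or `NA` for a clone with no in-tissue
#'   UMIs (excluded downstream).
#' @export
clone_tumor_fraction <- function(clone_id, mat, grid) {
  counts <- if (inherits(mat, "spatial_clone_matrix")) mat$counts else mat
  rows <- counts[counts$clone_id == clone_id, , drop = FALSE]
  idx <- match(rows$barcode, grid$barcode)
  in_tissue <- grid$in_tissue[idx] %in% TRUE
  total <- sum(rows$umi_count[in_tissue])
  if (total == 0) return(NA_real_)
  100 * sum(rows$umi_count[in_tissue & grid$is_tumor[idx] %in% TRUE]) / total
}

#' Per-clone spatial summary table
#'
#' @param mat Spatial clone matrix.
#' @param grid Spot grid.
#' @param phenotype Optional [classify_clone_phenotype()] table to join.
#' @return data.frame with one row per clone: `clone_id`, `call` (if
#'   phenotype given), `total_umis` (in tissue), `umis_in_tumor`,
#'   `tumor_fraction`.
#' @export
clone_spatial_summary <- function(mat, grid, phenotype = NULL) {
  counts <- if (inherits(mat, "spatial_clone_matrix")) mat$counts else mat
  idx <- match(counts$barcode, grid$barcode)
  counts <- counts[grid$in_tissue[idx] %in% TRUE, , drop = FALSE]
  idx <- match(counts$barcode, grid$barcode)
  dt <- data.table::data.table(clone_id = counts$clone_id,
                               umi = counts$umi_count,
                               tumor = grid$is_tumor[idx])
  s <- dt[, list(total_umis = sum(umi), umis_in_tumor = sum(umi[tumor])),
          by = "clone_id"]
  data.table::setorder(s, clone_id)
  s <- as.data.frame(s)
  s$tumor_fraction <- 100 * s$umis_in_tumor / s$total_umis
  if (!is.null(phenotype))
    s$call <- phenotype$call[match(s$clone_id, phenotype$clone_id)]
  s
}

#' Distribution of clone UMIs across tissue regions by phenotype group
#'
#' @param phenotype [classify_clone_phenotype()] table (`clone_id`, `call`).
#' @param mat Spatial clone matrix.
#' @param grid Spot grid (in-tissue spots are used; region labels kept in
#'   full).
#' @param groups Phenotype calls to tabulate (default AD and BC).
#' @return data.frame `group`, `region`, `umi_count`, `share` (percent;
#'   shares sum to 100 within each group). Groups without UMIs are omitted
#'   with a warning.
#' @export
region_umi_distribution <- function(phenotype, mat, grid,
                                    groups = c("AD", "BC")) {
  counts <- if (inherits(mat, "spatial_clone_matrix")) mat$counts else mat
  idx <- match(counts$barcode, grid$barcode)
  keep <- grid$in_tissue[idx] %in% TRUE
  counts <- counts[keep, , drop = FALSE]
  idx <- idx[keep]
  call <- phenotype$call[match(counts$clone_id, phenotype$clone_id)]
  region <- grid$region[idx]
  out <- NULL
  for (g in groups) {
    sel <- call %in% g
    if (!any(sel)) { warning("phenotype group without UMIs: ", g); next }
    tab <- tapply(counts$umi_count[sel], region[sel], sum)
    out <- rbind(out, data.frame(group = g, region = names(tab),
                                 umi_count = as.numeric(tab),
                                 share = 100 * as.numeric(tab) / sum(tab),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' UMI-weighted distances to the tumor border outside the parenchyma
#'
#' Expands each (clone, spot) UMI count at a non-tumor in-tissue spot into
#' one observation per UMI at that spot's border distance.
#'
#' @param clone_id Clones to include.
#' @param mat Spatial clone matrix.
#' @param grid Spot grid.
#' @return Numeric vector of distances (one entry per UMI).
#' @export
umi_border_distances <- function(clone_id, mat, grid) {
  counts <- if (inherits(mat, "spatial_clone_matrix")) mat$counts else mat
  counts <- counts[counts$clone_id %in% clone_id, , drop = FALSE]
  idx <- match(counts$barcode, grid$barcode)
  keep <- grid$in_tissue[idx] %in% TRUE & !(grid$is_tumor[idx] %in% TRUE)
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) return(numeric(0))
  d <- distance_to_tumor_border(grid, counts$barcode)
  rep(unname(d), counts$umi_count)
}

#' Weighted empirical cumulative distribution of UMI distances
#'
#' @param distances Numeric distances (already UMI-expanded, e.g.
#'   [umi_border_distances()]).
#' @param weights Optional nonnegative weights (UMI multiplicities).
#' @return data.frame `distance`, `cum_freq`: the right-continuous ECDF
#'   evaluated at the sorted unique distances; final value 1.
#' @export
distance_ecdf <- function(distances, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(distances))
  stopifnot(length(weights) == length(distances))
  keep <- weights > 0
  distances <- distances[keep]; weights <- weights[keep]
  if (length(distances) == 0L) stop("no qualifying UMIs for the ECDF")
  o <- order(distances)
  d <- distances[o]; w <- weights[o]
  agg <- tapply(w, d, sum)
  data.frame(distance = as.numeric(names(agg)),
             cum_freq = cumsum(as.numeric(agg)) / sum(w))
}

expand_weighted <- function(x, w) {
  if (is.null(w)) return(x)
  stopifnot(length(w) == length(x), all(w >= 0), all(w == round(w)))
  rep(x, w)
}

#' Two-sample Kolmogorov-Smirnov test on UMI-weighted samples
#'
#' D is the supremum absolute difference between the two empirical CDFs of
#' the UMI-expanded samples. The p-value uses the exact conditional
#' distribution when both expanded sizes are at most 25 and the asymptotic
#' Kolmogorov distribution with effective size `n*m/(n+m)` otherwise.
#'
#' @param x,y Numeric samples (distances).
#' @param wx,wy Optional integer multiplicities expanding each observation.
#' @return list with `statistic` (D), `p_value`, `n_x`, `n_y` (expanded
#'   sizes), `method`.
#' @export
ks_two_sample <- function(x, y, wx = NULL, wy = NULL) {
  x <- expand_weighted(x, wx)
  y <- expand_weighted(y, wy)
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), 0)
  fy <- vapply(pts, function(t) mean(y <= t), 0)
  D <- max(abs(fx - fy))
  if (n <= 25L && m <= 25L) {
    p <- 1 - stats::psmirnov(D - 1e-12, sizes = c(n, m),
                             z = c(x, y), two.sided = TRUE)
    method <- "exact"
  } else {
    ne <- n * m / (n + m)
    t <- sqrt(ne) * D
    kk <- 1:100
    p <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * t^2))
    p <- min(max(p, 0), 1)
    method <- "asymptotic"
  }
  list(statistic = D, p_value = p, n_x = n, n_y = m, method = method)
}

#' Mann-Whitney U test on per-clone tumor fractions
#'
#' \eqn{U = \sum_{i,j} [x_i > y_j] + \tfrac12 [x_i = y_j]}, with the
#' two-sided tie-corrected normal-approximation p-value (no continuity
#' correction).
#'
#' @param x,y Numeric vectors (one value per clone).
#' @return list with `U`, `p_value`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1      # all values tied: no evidence either way
  } else {
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p_value = min(p, 1), n_x = n1, n_y = n2)
}

#' Overall tumor share of gene-expression UMIs
#'
#' The dashed-line reference value: the percentage of all gene-expression
#' UMIs (per-spot totals) captured at tumor-parenchyma spots, among
#' in-tissue spots.
#'
#' @param spot_totals Named numeric vector of per-spot total UMIs.
#' @param grid Spot grid.
#' @return Percentage in `[0, 100]`.
#' @export
overall_umi_tumor_fraction <- function(spot_totals, grid) {
  idx <- match(names(spot_totals), grid$barcode)
  if (anyNA(idx)) stop("unknown spot barcode(s) in spot totals")
  keep <- grid$in_tissue[idx]
  tot <- sum(spot_totals[keep])
  if (tot == 0) stop("zero total gene-expression UMIs in tissue")
  100 * sum(spot_totals[keep & grid$is_tumor[idx]]) / tot
}

#' Detection filter for spatial gene expression
#'
#' A gene is kept iff its total count is at least 10 and it is expressed in
#' at least 3 spots (genes below 10 counts, or expressed in two or fewer
#' spots, are below the limit of detection).
#'
#' @param total Numeric vector of per-gene total counts.
#' @param n_spots Integer vector of spots with nonzero expression.
#' @param min_total,min_spots Thresholds (defaults 10 and 3).
#' @return Logical vector: `TRUE` for kept genes.
#' @export
filter_detected_genes <- function(total, n_spots,
                                  min_total = 10, min_spots = 3) {
  stopifnot(length(total) == length(n_spots))
  total >= min_total & n_spots >= min_spots
}

#' Tumor localization of the most expanded clones
#'
#' Clones are ranked by total in-tissue spatial UMIs (descending; ties
#' lexicographic on clone id) and the table restricted to the expansion
#' criterion. Rank 1 is the most expanded clone.
#'
#' @param mat Spatial clone matrix.
#' @param phenotype [classify_clone_phenotype()] table.
#' @param grid Spot grid.
#' @param top_n Keep the `top_n` most expanded clones, or
#' @param min_umis keep clones with at least this many in-tissue UMIs.
#' @param spot_totals Optional per-spot gene-expression totals; when given,
#'   the [overall_umi_tumor_fraction()] reference is attached as attribute
#'   `"reference_fraction"`.
#' @return data.frame `rank`, `clone_id`, `call`, `total_umis`,
#'   `tumor_fraction`.
#' @export
expanded_clone_localization <- function(mat, phenotype, grid,
                                        top_n = NULL, min_umis = NULL,
                                        spot_totals = NULL) {
  s <- clone_spatial_summary(mat, grid, phenotype)
  s <- s[order(-s$total_umis, s$clone_id), , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  if (!is.null(min_umis)) s <- s[s$total_umis >= min_umis, , drop = FALSE]
  if (!is.null(top_n)) s <- utils::head(s, top_n)
  out <- s[, c("rank", "clone_id", "call", "total_umis", "tumor_fraction")]
  row.names(out) <- NULL
  if (!is.null(spot_totals))
    attr(out, "reference_fraction") <-
      overall_umi_tumor_fraction(spot_totals, grid)
  out
}
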