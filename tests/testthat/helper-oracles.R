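# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

oracle_morisita_horn <- function(x, y) {
  keys <- union(names(x), names(y))
  num <- 0; sx <- 0; sy <- 0
  for (k in keys) {
    xi <- if (k %in% names(x)) x[[k]] else 0
    yi <- if (k %in% names(y)) y[[k]] else 0
    num <- num + xi * yi
    sx <- sx + xi^2
    sy <- sy + yi^2
  }
  X <- sum(unlist(x)); Y <- sum(unlist(y))
  2 * num / ((sx / X^2 + sy / Y^2) * X * Y)
}

oracle_cefx <- function(pos, neg, min_count = 2, min_ratio = 5) {
  out <- character(0)
  P <- sum(unlist(pos)); N <- sum(unlist(neg))
  for (k in names(pos)) {
    cp <- pos[[k]]
    cn <- if (k %in% names(neg)) neg[[k]] else 0
    fp <- cp / P
    fn <- if (N > 0) cn / N else 0
    if (cp >= min_count && fp >= min_ratio * fn) out <- c(out, k)
  }
  sort(out)
}

oracle_min_tumor_distance <- function(grid, barcode) {
  i <- which(grid$barcode == barcode)
  if (grid$is_tumor[i]) return(0)
  best <- Inf
  for (j in which(grid$is_tumor)) {
    d <- sqrt((grid$x[i] - grid$x[j])^2 + (grid$y[i] - grid$y[j])^2)
    if (d < best) best <- d
  }
  best
}

oracle_mann_whitney_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# exhaustive all-offsets ungapped scan: best contiguous +1/-1 segment over
# every possible diagonal, via prefix-sum differences over all (start, end)
oracle_align_score <- function(read, ref) {
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  best <- NULL
  for (d in (1 - length(fc)):(length(rc) - 1)) {
    rs <- max(1, 1 + d); re <- min(length(rc), length(fc) + d)
    if (re < rs) next
    v <- ifelse(rc[rs:re] == fc[(rs - d):(re - d)], 1, -1)
    prefix <- c(0, cumsum(v))
    diffs <- outer(prefix, prefix, "-")   # diffs[e+1, s] = sum v[s..e]
    s <- max(diffs[lower.tri(diffs)])
    if (is.null(best) || s > best) best <- s
  }
  best
}

random_repertoire_counts <- function(n_keys = 8, max_count = 20) {
  keys <- paste0("TRBV", sample(30, n_keys), "_TRBJ", sample(2, n_keys,
                 replace = TRUE), "_CASS", replicate(n_keys, paste(
                   sample(LETTERS[1:20], 5, replace = TRUE), collapse = "")))
  keys <- make.unique(keys, sep = "X")
  setNames(sample.int(max_count, n_keys, replace = TRUE), keys)
}

tiny_grid <- function(n_rows = 6, n_cols = 6, tumor_rows = 1:2,
                      pitch = 100) {
  positions <- expand.grid(r = seq_len(n_rows) - 1, c0 = seq_len(n_cols) - 1)
  positions <- data.frame(
    barcode = sprintf("S%03d", seq_len(nrow(positions))),
    in_tissue = TRUE,
    array_row = positions$r,
    array_col = positions$c0 * 2 + positions$r %% 2,
    pxl_row_in_fullres = 0, pxl_col_in_fullres = 0)
  regions <- data.frame(
    barcode = positions$barcode,
    region = ifelse(positions$array_row %in% (tumor_rows - 1),
                    "tumor", "stroma"))
  build_spot_grid(positions, regions, tumor_labels = "tumor",
                  pitch_um = pitch)
}
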