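test_that("simulated tissue geometry follows the disc definition", {
  g0 <- simulate_tissue(9, 9, tumor_radius_um = 0)
  expect_equal(sum(g0$is_tumor), 1L)
  g_all <- simulate_tissue(6, 6, tumor_radius_um = 1e6)
  expect_true(all(g_all$is_tumor))
  # tumor spot fraction approximates the disc area fraction
  g <- simulate_tissue(40, 40, tumor_radius_um = 800, pitch_um = 100)
  spot_area <- 100^2 * sqrt(3) / 2         # hexagonal lattice cell
  expected <- pi * 800^2 / spot_area
  expect_gt(sum(g$is_tumor), expected * 0.85)
  expect_lt(sum(g$is_tumor), expected * 1.15)
  expect_error(simulate_tissue(0, 5), "degenerate")
})

test_that("whitelists keep pairwise Hamming distance >= 3", {
  set.seed(19)
  wl <- simulate_barcode_whitelist(60, barcode_len = 12, min_dist = 3)
  m <- do.call(rbind, strsplit(wl, ""))
  for (i in seq_len(nrow(m) - 1)) {
    d <- rowSums(m[(i + 1):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    expect_true(all(d >= 3))
  }
})

test_that("Zipf repertoires have the configured spectrum", {
  set.seed(20)
  uni <- simulate_repertoire(20, zipf_exponent = 0, total_umis = 20000)
  expect_gt(min(uni$n_umis), 800)   # uniform multinomial, 1000 expected
  expect_lt(max(uni$n_umis), 1200)
  one <- simulate_repertoire(1, umis_per_clone = 7)
  expect_equal(clone_rank_cumulative(
    aggregate_repertoire(one$clone_id, one$n_umis))$cumulative_frequency, 1)
  expect_false(anyDuplicated(simulate_repertoire(100)$clone_id) > 0)
})

test_that("UMI placement respects per-phenotype tumor probabilities", {
  set.seed(21)
  g <- tiny_grid(8, 8, tumor_rows = 1:4)
  clones <- data.frame(clone_id = c("K", "L"), phenotype = c("AD", "BC"),
                       n_umis = c(500, 500))
  placed <- simulate_spatial_umis(clones, g, p_tumor = c(AD = 1, BC = 0))
  expect_equal(clone_tumor_fraction("K", placed$counts, g), 100)
  expect_equal(clone_tumor_fraction("L", placed$counts, g), 0)
})

test_that("generators are deterministic and FASTQ is well-formed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- simulate_spatial_dataset(d1, seed = 33, n_rows = 6, n_cols = 6,
                                 tumor_radius_um = 200, n_clones = 6,
                                 total_umis = 80, reads_per_umi = 2,
                                 err_barcode = 0.01, err_insert = 0.002)
  g2 <- simulate_spatial_dataset(d2, seed = 33, n_rows = 6, n_cols = 6,
                                 tumor_radius_um = 200, n_clones = 6,
                                 total_umis = 80, reads_per_umi = 2,
                                 err_barcode = 0.01, err_insert = 0.002)
  for (f in c("r1", "r2", "whitelist", "positions", "clone_truth"))
    expect_identical(readLines(g1$paths[[f]]),
                     readLines(g2$paths[[f]]))
  # parses under a standard FASTQ reader; R1 length = barcode + UMI
  r1 <- Biostrings::readDNAStringSet(g1$paths$r1, format = "fastq")
  expect_equal(unique(Biostrings::width(r1)), 16 + 12)
  expect_equal(length(r1), 2 * nrow(g1$placements))
})

test_that("reads-per-UMI bookkeeping and barcode error rate are honored", {
  set.seed(22)
  gt <- simulate_spatial_dataset(withr::local_tempdir(), seed = 34,
                                 n_rows = 8, n_cols = 8,
                                 tumor_radius_um = 250, n_clones = 10,
                                 total_umis = 1000, reads_per_umi = 3,
                                 err_barcode = 0.01)
  r1 <- read_fastq_seqs(gt$paths$r1)
  expect_equal(nrow(r1), 3 * nrow(gt$placements))
  obs <- substr(r1$seq, 1, 16)
  truth <- gt$truth_map$barcode[match(r1$read_id, gt$truth_map$read_id)]
  frac_err <- mean(obs != truth)
  expect_gt(frac_err, 0.12)          # 1 - 0.99^16 = 0.149
  expect_lt(frac_err, 0.18)
})

test_that("planted CEFX-specific sets are recovered exactly", {
  set.seed(23)
  for (i in 1:50) {
    clones <- simulate_repertoire(12, umis_per_clone = 1)
    cefx <- simulate_cefx_tables(clones, n_specific = sample(0:5, 1))
    expect_identical(cefx_specific_clones(cefx$pos, cefx$neg),
                     cefx$specific)
  }
})

test_that("full error-free round trip reproduces planted spatial truth", {
  gt <- simulate_spatial_dataset(withr::local_tempdir(), seed = 35,
                                 n_rows = 10, n_cols = 10,
                                 tumor_radius_um = 300, n_clones = 15,
                                 umis_per_clone = 30, reads_per_umi = 2,
                                 p_tumor = c(AD = 0.9, BC = 0.1))
  mat <- run_extract(gt$paths$r1, gt$paths$whitelist, r2 = gt$paths$r2,
                     refs = toy_segment_reference())
  got <- mat$counts[order(mat$counts$clone_id, mat$counts$barcode),
                    c("clone_id", "barcode", "umi_count")]
  expect_equal(got, gt$counts, ignore_attr = TRUE)
  # planted tumor fractions propagate through the statistics layer
  phen <- run_link(mat, gt$cells)
  expect_equal(phen$call[match(gt$clones$clone_id, phen$clone_id)],
               gt$clones$phenotype)
  st <- run_stats(mat, phen, gt$grid, top_n = 30)
  expect_lt(st$mann_whitney$p_value, 0.01)
  expect_gt(st$pooled_tumor_share["AD"], st$pooled_tumor_share["BC"])
})
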