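test_that("read 1 splits positionally into barcode and UMI", {
  s28 <- paste0(strrep("A", 16), strrep("C", 12))
  p <- parse_read1(s28)
  expect_equal(p$barcode, strrep("A", 16))
  expect_equal(p$umi, strrep("C", 12))
  p2 <- parse_read1(paste0(s28, "GG"))           # trailing bases ignored
  expect_equal(p2$umi, strrep("C", 12))
  p3 <- parse_read1(strrep("A", 20))
  expect_true(p3$too_short)
  expect_true(is.na(p3$barcode))
})

test_that("barcode correction: exact, unique 1-neighbor, ambiguity, N", {
  wl <- barcode_whitelist(c("AAAAAAAA", "CCCCCCCC", "AAAATTTT"))
  expect_equal(unname(correct_barcode("AAAAAAAA", wl)[1]), "AAAAAAAA")
  expect_equal(unname(correct_barcode("AAAAAAAG", wl)[1]), "AAAAAAAA")
  # distance-1 from two entries: AAAAATTT is 1 from AAAATTTT? no; craft tie
  wl2 <- barcode_whitelist(c("AAAA", "AAAT"))
  expect_true(is.na(correct_barcode("AAAG", wl2)[1])) # 1 from both
  # N counts as a mismatch but still corrects against a unique neighbor
  expect_equal(unname(correct_barcode("AAAAAAAN", wl)[1]), "AAAAAAAA")
  expect_true(is.na(correct_barcode("AAANNAAA", wl)[1]))  # two Ns
  # wrong length
  out <- correct_barcode("AAAA", wl)
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "reason")[1], "barcode_length")
})

test_that("clone read maps deduplicate and drop conflicting read ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tclone_id",
               "r1\tK", "r2\tK", "r2\tK", "r3\tK", "r3\tL", "r4\tM"), f)
  m <- load_clone_read_map(f)
  expect_equal(sort(names(m)), c("r1", "r2", "r4"))
  expect_equal(attr(m, "n_conflicts"), 1L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read\tclone", "r1\tK"), bad)
  expect_error(load_clone_read_map(bad), "read_id")
})

test_that("UMI counts are distinct-UMI counts per (clone, spot)", {
  wl <- barcode_whitelist(c(strrep("A", 16), strrep("C", 16)))
  r1 <- function(bc, umi) paste0(bc, umi)
  reads <- data.frame(
    read_id = paste0("r", 1:4),
    seq = c(r1(strrep("A", 16), strrep("G", 12)),   # c1 s1 U1
            r1(strrep("A", 16), strrep("G", 12)),   # duplicate triple
            r1(strrep("A", 16), strrep("T", 12)),   # c1 s1 U2
            r1(strrep("C", 16), strrep("G", 12))))  # same UMI, other spot
  cmap <- setNames(rep("c1", 4), paste0("r", 1:4))
  mat <- build_spatial_clone_matrix(reads, cmap, wl)
  expect_equal(mat$counts$umi_count[mat$counts$barcode == strrep("A", 16)], 2)
  expect_equal(mat$counts$umi_count[mat$counts$barcode == strrep("C", 16)], 1)
  expect_equal(unname(mat$qc["assigned"]), 4L)
})

test_that("reads without clone assignment are counted as no_clone", {
  wl <- barcode_whitelist(strrep("A", 16))
  reads <- data.frame(read_id = c("r1", "r2"),
                      seq = rep(paste0(strrep("A", 16), strrep("G", 12)), 2))
  mat <- build_spatial_clone_matrix(reads, c(r1 = "c1"), wl)
  expect_equal(unname(mat$qc["no_clone"]), 1L)
  expect_equal(sum(mat$counts$umi_count), 1)
})

test_that("matrix is invariant to read order and PCR duplication", {
  set.seed(8)
  gt <- simulate_spatial_dataset(withr::local_tempdir(), seed = 21,
                                 n_rows = 8, n_cols = 8,
                                 tumor_radius_um = 250, n_clones = 8,
                                 total_umis = 150, reads_per_umi = 2)
  wl <- barcode_whitelist(gt$paths$whitelist)
  r1 <- read_fastq_seqs(gt$paths$r1)
  cmap <- setNames(gt$truth_map$clone_id, gt$truth_map$read_id)
  base <- build_spatial_clone_matrix(r1, cmap, wl)
  perm <- r1[sample(nrow(r1)), ]
  expect_equal(build_spatial_clone_matrix(perm, cmap, wl)$counts,
               base$counts)
  dup <- rbind(r1, r1[sample(nrow(r1), 50), ])
  expect_equal(build_spatial_clone_matrix(dup, cmap, wl)$counts,
               base$counts)
  # conservation: total equals distinct planted triples
  expect_equal(sum(base$counts$umi_count), nrow(gt$placements))
})

test_that("error-free synthetic reads reproduce the planted matrix", {
  gt <- simulate_spatial_dataset(withr::local_tempdir(), seed = 22,
                                 n_rows = 10, n_cols = 10,
                                 tumor_radius_um = 300, n_clones = 12,
                                 total_umis = 300, reads_per_umi = 3)
  mat <- run_extract(gt$paths$r1, gt$paths$whitelist,
                     clone_map = gt$paths$read_map)
  got <- mat$counts[order(mat$counts$clone_id, mat$counts$barcode), ]
  want <- gt$counts[order(gt$counts$clone_id, gt$counts$barcode), ]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("matrix and QC writers emit readable TSV/MTX", {
  gt <- simulate_spatial_dataset(withr::local_tempdir(), seed = 23,
                                 n_rows = 6, n_cols = 6,
                                 tumor_radius_um = 200, n_clones = 5,
                                 total_umis = 60, reads_per_umi = 1)
  mat <- run_extract(gt$paths$r1, gt$paths$whitelist,
                     clone_map = gt$paths$read_map)
  out <- withr::local_tempdir()
  write_clone_matrix(mat, out)
  tsv <- read.delim(file.path(out, "spatial_tcr_matrix.tsv"))
  expect_equal(sum(tsv$umi_count), sum(mat$counts$umi_count))
  mm <- Matrix::readMM(file.path(out, "spatial_tcr_matrix.mtx"))
  expect_equal(sum(mm), sum(mat$counts$umi_count))
  write_qc_report(mat$qc, file.path(out, "qc.tsv"))
  qc <- read.delim(file.path(out, "qc.tsv"))
  expect_equal(sum(qc$reads), sum(mat$qc))
})
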