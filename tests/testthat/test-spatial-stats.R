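test_that("tumor-border distance is the nearest tumor-spot distance", {
  g <- tiny_grid(6, 6, tumor_rows = 1)
  d <- distance_to_tumor_border(g)
  expect_true(all(d[g$barcode[g$is_tumor]] == 0))
  # 3-4-5 triangle on a hand-built grid
  g2 <- data.frame(barcode = c("t", "s"), x = c(300, 0), y = c(400, 0),
                   in_tissue = TRUE, region = c("tumor", "stroma"),
                   is_tumor = c(TRUE, FALSE))
  expect_equal(unname(distance_to_tumor_border(g2, "s")), 500)
  expect_error(distance_to_tumor_border(g2[2, , drop = FALSE]), "no tumor")
  # oracle equivalence on random tumor labelings
  set.seed(12)
  for (i in 1:10) {
    g3 <- tiny_grid(8, 8, tumor_rows = sample(8, 2))
    d3 <- distance_to_tumor_border(g3)
    for (b in sample(g3$barcode, 12))
      expect_equal(unname(d3[b]), oracle_min_tumor_distance(g3, b))
  }
})

test_that("clone tumor fraction counts in-tissue UMIs only", {
  g <- tiny_grid(4, 4, tumor_rows = 1:2)
  tum <- g$barcode[g$is_tumor][1:2]
  str <- g$barcode[!g$is_tumor][1:2]
  counts <- data.frame(clone_id = "K",
                       barcode = c(tum, str),
                       umi_count = c(5, 3, 1, 1))
  expect_equal(clone_tumor_fraction("K", counts, g), 80)
  all_tum <- data.frame(clone_id = "K", barcode = tum, umi_count = c(2, 2))
  expect_equal(clone_tumor_fraction("K", all_tum, g), 100)
  # out-of-tissue UMIs are excluded from both numerator and denominator
  g$in_tissue[match(str[1], g$barcode)] <- FALSE
  g$is_tumor[match(str[1], g$barcode)] <- FALSE
  expect_equal(clone_tumor_fraction("K", counts, g),
               100 * 8 / 9)
  expect_true(is.na(clone_tumor_fraction("absent", counts, g)))
})

test_that("random UMI placement recovers the planted tumor probability", {
  set.seed(13)
  g <- tiny_grid(10, 10, tumor_rows = 1:5)
  clones <- data.frame(clone_id = "K", phenotype = "AD", n_umis = 10000)
  placed <- simulate_spatial_umis(clones, g, p_tumor = c(AD = 0.5))
  f <- clone_tumor_fraction("K", placed$counts, g)
  expect_gt(f, 48); expect_lt(f, 52)   # ~4 sd of binomial noise
})

test_that("region UMI distribution rows normalize to 100 percent", {
  g <- tiny_grid(4, 4, tumor_rows = 1)
  ph <- data.frame(clone_id = c("K", "L"), call = c("AD", "BC"))
  counts <- data.frame(
    clone_id = c("K", "K", "L"),
    barcode = c(g$barcode[g$is_tumor][1], g$barcode[!g$is_tumor][1],
                g$barcode[g$is_tumor][2]),
    umi_count = c(3, 1, 2))
  tab <- region_umi_distribution(ph, counts, g)
  for (grp in unique(tab$group))
    expect_equal(sum(tab$share[tab$group == grp]), 100)
  expect_equal(tab$share[tab$group == "AD" & tab$region == "tumor"], 75)
  expect_equal(tab$share[tab$group == "BC" & tab$region == "tumor"], 100)
  expect_warning(region_umi_distribution(ph, counts, g,
                                         groups = c("AD", "BC", "X")),
                 "without UMIs")
})

test_that("distance ECDF is the UMI-expanded empirical CDF", {
  e <- distance_ecdf(c(100, 200), weights = c(2, 1))
  expect_equal(e$cum_freq[e$distance == 100], 2 / 3)
  expect_equal(e$cum_freq[e$distance == 200], 1)
  single <- distance_ecdf(50)
  expect_equal(single$cum_freq, 1)
  expect_error(distance_ecdf(numeric(0)), "no qualifying")
  # equals the unweighted ECDF of the expanded sample
  set.seed(14)
  d <- sample(100:500, 8); w <- sample(1:4, 8, replace = TRUE)
  e2 <- distance_ecdf(d, w)
  F <- stats::ecdf(rep(d, w))
  expect_equal(e2$cum_freq, unname(F(e2$distance)))
})

test_that("KS statistic and p agree with stats::ks.test conventions", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:3, 11:14)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(sample(5:20, 1)); y <- rnorm(sample(5:20, 1), 0.5)
    a <- ks_two_sample(x, y)
    b <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
    expect_equal(a$statistic, unname(b$statistic))
    expect_equal(a$p_value, b$p.value, tolerance = 1e-10)
    x2 <- rnorm(40); y2 <- rnorm(60, 0.3)
    a2 <- ks_two_sample(x2, y2)
    b2 <- suppressWarnings(stats::ks.test(x2, y2, exact = FALSE))
    expect_equal(a2$p_value, b2$p.value, tolerance = 1e-4)
  }
  # weights expand observations
  expect_equal(ks_two_sample(c(1, 2), c(2, 3), wx = c(2, 1), wy = c(1, 2)),
               ks_two_sample(c(1, 1, 2), c(2, 3, 3)))
})

test_that("Mann-Whitney U matches brute force and wilcox.test", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(5, c(1, 2))$U, 2)
  set.seed(16)
  for (i in 1:20) {
    x <- sample(0:10, sample(3:10, 1), replace = TRUE)
    y <- sample(0:10, sample(3:10, 1), replace = TRUE)
    a <- mann_whitney_u(x, y)
    expect_equal(a$U, oracle_mann_whitney_U(x, y))
    b <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
    expect_equal(a$p_value, b$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("overall gene-expression tumor share sums per-spot totals", {
  g <- tiny_grid(4, 4, tumor_rows = 1:2)
  tot <- setNames(rep(10, nrow(g)), g$barcode)
  expect_equal(overall_umi_tumor_fraction(tot, g), 50)
  tot2 <- setNames(ifelse(g$is_tumor, 5, 0), g$barcode)
  expect_equal(overall_umi_tumor_fraction(tot2, g), 100)
  set.seed(17)
  tot3 <- setNames(rpois(nrow(g), 50), g$barcode)
  expect_equal(overall_umi_tumor_fraction(tot3, g),
               100 * sum(tot3[g$is_tumor]) / sum(tot3))
})

test_that("gene detection filter keeps >=10 counts in >=3 spots", {
  expect_false(filter_detected_genes(9, 5))
  expect_false(filter_detected_genes(15, 2))
  expect_true(filter_detected_genes(10, 3))
  expect_equal(filter_detected_genes(c(9, 10, 100, 10), c(3, 3, 2, 2)),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("expanded-clone table ranks by UMIs and carries fractions", {
  g <- tiny_grid(4, 4, tumor_rows = 1:2)
  tum <- g$barcode[g$is_tumor][1]
  str <- g$barcode[!g$is_tumor][1]
  counts <- data.frame(
    clone_id = c("a", "a", "b", "c"),
    barcode = c(tum, str, tum, str),
    umi_count = c(8, 2, 5, 1))
  ph <- data.frame(clone_id = c("a", "b", "c"), call = c("AD", "BC", "AD"))
  tab <- expanded_clone_localization(counts, ph, g, top_n = 2)
  expect_equal(tab$clone_id, c("a", "b"))
  expect_equal(tab$rank, 1:2)
  expect_equal(tab$tumor_fraction,
               c(clone_tumor_fraction("a", counts, g),
                 clone_tumor_fraction("b", counts, g)))
  tot <- setNames(rep(1, nrow(g)), g$barcode)
  tab2 <- expanded_clone_localization(counts, ph, g, min_umis = 5,
                                      spot_totals = tot)
  expect_equal(tab2$clone_id, c("a", "b"))
  expect_equal(attr(tab2, "reference_fraction"), 50)
})

test_that("statistics are invariant to clone relabeling and spot order", {
  set.seed(18)
  g <- tiny_grid(8, 8, tumor_rows = 1:3)
  clones <- data.frame(clone_id = paste0("K", 1:6),
                       phenotype = rep(c("AD", "BC"), 3),
                       n_umis = 40)
  placed <- simulate_spatial_umis(clones, g)
  ph <- data.frame(clone_id = clones$clone_id, call = clones$phenotype)
  s1 <- clone_spatial_summary(placed$counts, g, ph)
  # permute spot rows and rename clones consistently
  perm <- placed$counts[sample(nrow(placed$counts)), ]
  perm$clone_id <- paste0("Z", perm$clone_id)
  ph2 <- ph; ph2$clone_id <- paste0("Z", ph2$clone_id)
  s2 <- clone_spatial_summary(perm, g, ph2)
  s2$clone_id <- sub("^Z", "", s2$clone_id)
  s2 <- s2[order(s2$clone_id), ]
  expect_equal(s2$tumor_fraction, s1$tumor_fraction, ignore_attr = TRUE)
  d1 <- sort(umi_border_distances(ph$clone_id[ph$call == "AD"],
                                  placed$counts, g))
  d2 <- sort(umi_border_distances(ph2$clone_id[ph2$call == "AD"], perm, g))
  expect_equal(d1, d2)
})
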