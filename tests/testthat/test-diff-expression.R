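test_that("region counting increments every overlapped region", {
  regions <- gintervals("chr1", c(100, 150, 1000), c(200, 250, 1100), "+",
                        c("g1", "g2", "g3"))
  reads <- gintervals("chr1", c(180, 1050), c(210, 1080), "+",
                      c("r1", "r2"))
  counts <- count_reads_per_region(reads, regions)
  expect_equal(counts, c(1, 1, 1), ignore_attr = TRUE)  # r1 hits g1 and g2
  expect_equal(attr(counts, "total"), 2)    # totals stay the read count
  none <- count_reads_per_region(
    gintervals("chr9", 1, 30, "+", "far"), regions)
  expect_equal(none, c(0, 0, 0), ignore_attr = TRUE)
  expect_error(count_reads_per_region(reads, rbind(regions, regions)),
               "distinct")
})

test_that("mean normalization scales both libraries to the average total", {
  regions <- gintervals("chr1", c(0, 100), c(50, 200), "+", c("a", "b"))
  tab <- count_table(regions, c(10, 20), c(40, 20), 100, 200)
  got <- normalize_mean(tab)
  expect_equal(got$counts_a, c(10, 20) * 1.5)
  expect_equal(got$counts_b, c(40, 20) * 0.75)
  expect_equal(got$total_a, got$total_b)
  eq <- normalize_mean(count_table(regions, c(5, 5), c(7, 3), 10, 10))
  expect_equal(eq$counts_a, c(5, 5))   # equal totals: identity
  expect_error(normalize_mean(count_table(regions, c(0, 0), c(1, 1), 0, 2)),
               "zero")
})

test_that("interquartile normalization equalizes the IQR sums", {
  regions <- gintervals("chr1", 100 * (1:8), 100 * (1:8) + 50, "+",
                        sprintf("g%d", 1:8))
  a <- c(0, 1, 2, 3, 4, 5, 6, 100)
  b <- c(0, 2, 4, 6, 8, 10, 12, 10)
  tab <- count_table(regions, a, b, sum(a), sum(b))
  got <- normalize_interquartile(tab)
  # hand oracle: rank regions by (a+b)/2 ascending, IQR = 0-based ranks 2..5
  ord <- order((a + b) / 2)
  iqr <- ord[3:6]
  f <- sum(a[iqr]) / sum(b[iqr])
  expect_equal(got$counts_b, b * f)
  expect_equal(got$counts_a, a)
  expect_equal(sum(got$counts_a[iqr]), sum(got$counts_b[iqr]))
  ident <- normalize_interquartile(count_table(regions, a, a))
  expect_equal(ident$counts_b, a)  # identical samples: factor 1
  expect_error(normalize_interquartile(count_table(regions[1:3], a[1:3],
                                                   b[1:3])), "4 regions")
})

test_that("window-averaged counts equal the analytic uniform value", {
  # region of length 100 next to a length-50 region fixing w = 50;
  # 1-nt reads at every position of the long region
  regions <- gintervals("chr1", c(1000, 5000), c(1100, 5050), "+",
                        c("long", "short"))
  reads <- gintervals("chr1", 1000:1099, 1001:1100, "+",
                      sprintf("r%d", 1:100))
  tab <- window_averaged_counts(reads, reads, regions)
  expect_equal(tab$counts_a[1], 50)
  expect_equal(tab$counts_a[1], tab$counts_b[1])
  # region length == w: plain overlap count (single placement)
  short_reads <- gintervals("chr1", c(5000, 5010), c(5030, 5040), "+")
  tab2 <- window_averaged_counts(short_reads, short_reads, regions)
  expect_equal(tab2$counts_a[2], 2)
  # linearity: duplicating every read doubles the mean exactly
  tab3 <- window_averaged_counts(rbind(reads, reads), reads, regions)
  expect_equal(tab3$counts_a, 2 * tab$counts_a)
})

test_that("the exact test matches enumeration and handles degeneracy", {
  expect_equal(fisher_exact(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact(0, 0, 10, 10), 1.0)
  expect_equal(fisher_exact(3, 0, 0, 0), 1.0)
  # 61-table enumeration oracle
  expect_equal(fisher_exact(10, 50, 90, 50), oracle_fisher(10, 50, 90, 50),
               tolerance = 1e-7)
  set.seed(88)
  for (k in 1:200) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    ra <- sample(0:140, 1); rb <- sample(0:140, 1)
    expect_equal(fisher_exact(a, b, ra, rb), oracle_fisher(a, b, ra, rb),
                 tolerance = 1e-7,
                 info = sprintf("(%d,%d,%d,%d)", a, b, ra, rb))
  }
  # independent library cross-check
  for (tb in list(c(10, 50, 90, 50), c(3, 17, 40, 12), c(0, 9, 20, 11))) {
    expect_equal(
      fisher_exact(tb[1], tb[2], tb[3], tb[4]),
      stats::fisher.test(matrix(tb, nrow = 2, byrow = TRUE))$p.value,
      tolerance = 1e-6)
  }
  # one-sided alternatives bound the two-sided value
  expect_lt(fisher_exact(30, 5, 70, 95, alternative = "greater"),
            fisher_exact(30, 5, 70, 95))
})

test_that("BH adjustment reproduces the step-up values in input order", {
  rec <- data.table::data.table(name = c("d", "c", "b", "a"),
                                p = c(0.04, 0.01, 0.03, 0.02))
  got <- fdr_filter(rec, alpha = 0.05)
  expect_equal(got$q, rep(0.04, 4))
  expect_equal(got$name, c("d", "c", "b", "a"))  # order preserved
  one <- fdr_filter(data.table::data.table(p = 0.2), alpha = 0.5)
  expect_equal(one$q, 0.2)
  dull <- fdr_filter(data.table::data.table(p = rep(1, 5)), alpha = 0.99)
  expect_false(any(dull$significant))
})

test_that("a planted 4-fold region is recovered in nearly every replicate", {
  set.seed(1234)
  n_regions <- 50
  depth <- 50
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    ca <- rpois(n_regions, depth)
    cb <- rpois(n_regions, depth * c(4, rep(1, n_regions - 1)))
    regions <- gintervals("chr1", 1000 * (1:n_regions),
                          1000 * (1:n_regions) + 500, "+",
                          sprintf("g%d", 1:n_regions))
    tab <- normalize_mean(count_table(regions, ca, cb, sum(ca), sum(cb)))
    res <- diff_expr_from_table(tab, alpha = 0.05)
    if (res$significant[1]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
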