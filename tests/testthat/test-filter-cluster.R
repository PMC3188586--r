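reads_with_sizes <- function(sizes) {
  starts <- seq(0, by = 1000, length.out = length(sizes))
  gintervals("chr1", starts, starts + sizes, "+",
             sprintf("r%d", seq_along(sizes)))
}

test_that("size filter keeps the inclusive window and preserves order", {
  x <- reads_with_sizes(c(25, 28, 29, 30, 31))
  kept <- filter_by_size(x, 28, 30)
  expect_equal(iv_size(kept), c(28, 29, 30))
  expect_equal(kept$name, c("r2", "r3", "r4"))
  expect_equal(nrow(filter_by_size(x)), 5)                 # 0..Inf identity
  expect_equal(nrow(filter_by_size(gintervals_empty(), 28, 30)), 0)
  expect_error(filter_by_size(x, 30, 28), "min_size > max_size")
})

test_that("tag filter applies every present constraint and tallies drops", {
  x <- gintervals("chr1", c(0, 10, 20), c(5, 15, 25), "+",
                  c("a", "b", "c"),
                  tags = list(list(nbOccurrences = 1),
                              list(nbOccurrences = 3),
                              list(nbOccurrences = 1)))
  expect_equal(filter_by_tags(x, exact_hits = 1)$name, c("a", "c"))
  y <- gintervals("chr1", c(0, 10, 20), c(5, 15, 25), "+",
                  tags = list(list(nbMismatches = 0),
                              list(nbMismatches = 1),
                              list(nbMismatches = 2)))
  expect_equal(nrow(filter_by_tags(y, max_mismatches = 0)), 1)
  z <- gintervals("chr1", c(0, 10), c(5, 15), "+", c("tagged", "untagged"),
                  tags = list(list(nbOccurrences = 1), NULL))
  got <- filter_by_tags(z, exact_hits = 1)
  expect_equal(got$name, "tagged")
  expect_equal(attr(got, "dropped_missing_tag"), 1)
})

test_that("overlap selection honours flanks, strand and the complement law", {
  gene <- gintervals("chr1", 1000, 2000, "+", "gene1")
  promoter_read <- gintervals("chr1", 510, 540, "+", "p")
  expect_equal(nrow(select_by_overlap(promoter_read, gene, "keep")), 0)
  kept <- select_by_overlap(promoter_read, gene, "keep", upstream = 500)
  expect_equal(kept$name, "p")
  expect_equal(kept$tags[[1]]$overlapping_refs, "gene1")
  # strand-specific: a minus read against a plus reference is not kept
  minus_read <- gintervals("chr1", 1500, 1530, "-", "m")
  expect_equal(nrow(select_by_overlap(minus_read, gene, "keep",
                                      strand_specific = TRUE)), 0)
  expect_equal(nrow(select_by_overlap(minus_read, gene, "keep")), 1)
  # keep and exclude partition any input
  set.seed(5)
  q <- df_to_gintervals(random_intervals_df(300, max_coord = 50000))
  refs <- df_to_gintervals(random_intervals_df(40, max_coord = 50000))
  kept <- select_by_overlap(q, refs, "keep", upstream = 100)
  excl <- select_by_overlap(q, refs, "exclude", upstream = 100)
  expect_equal(nrow(kept) + nrow(excl), nrow(q))
  expect_equal(sort(c(kept$name, excl$name)), sort(q$name))
  expect_length(intersect(kept$name, excl$name), 0)
})

test_that("clustering merges overlap-linked reads and respects strand", {
  x <- gintervals("chr1", c(10, 15, 40), c(20, 30, 50), "+",
                  c("a", "b", "c"))
  cl <- clusterize(x, max_distance = 0)
  expect_equal(cl$start, c(10, 40))
  expect_equal(cl$end, c(30, 50))
  expect_equal(cl$n_elements, c(2, 1))
  expect_equal(sort(cl$member_names[[1]]), c("a", "b"))
  mixed <- gintervals("chr1", c(10, 15), c(20, 30), c("+", "-"))
  expect_equal(nrow(clusterize(mixed, 0, strand_specific = TRUE)), 2)
  expect_equal(nrow(clusterize(mixed, 0, strand_specific = FALSE)), 1)
  # book-ended reads only merge with a positive window
  adj <- gintervals("chr1", c(10, 20), c(20, 30), "+")
  expect_equal(nrow(clusterize(adj, 0)), 2)
  expect_equal(nrow(clusterize(adj, 1)), 1)
})

test_that("clustering matches the union-find oracle and conserves reads", {
  set.seed(31)
  df <- random_intervals_df(2000, n_chroms = 2, max_coord = 200000,
                            max_len = 400)
  x <- df_to_gintervals(df)
  for (maxd in c(0, 50)) {
    cl <- clusterize(x, max_distance = maxd, strand_specific = FALSE)
    want <- oracle_cluster(df, maxd, strand_specific = FALSE)
    expect_equal(nrow(cl), length(want))
    expect_equal(cl$start, unname(vapply(want, `[[`, numeric(1), "start")))
    expect_equal(cl$end, unname(vapply(want, `[[`, numeric(1), "end")))
    expect_equal(cl$n_elements,
                 as.integer(vapply(want, `[[`, numeric(1), "n")),
                 ignore_attr = TRUE)
    expect_equal(sum(cl$n_elements), nrow(x))  # conservation
    # idempotence on the cluster footprints
    cl2 <- clusterize(cl, max_distance = maxd, strand_specific = FALSE)
    expect_equal(cl2$start, cl$start)
    expect_equal(cl2$end, cl$end)
  }
})

test_that("cluster filtering applies member and unique-mapper thresholds", {
  mk <- function(n, uniq) {
    out <- gintervals("chr1", 1, 100, "+", "c")
    out[, n_elements := n]
    out[, has_unique_mapper := uniq]
    out
  }
  cl <- rbind(mk(3, TRUE), mk(10, TRUE), mk(27, FALSE))
  expect_equal(nrow(filter_clusters(cl, min_elements = 10)), 2)
  expect_equal(nrow(filter_clusters(cl, min_elements = 10,
                                    require_unique_mapper = TRUE)), 1)
  expect_equal(nrow(filter_clusters(cl)), 3)  # identity defaults
})

test_that("bidirectional merge reports overlap and divergent patterns", {
  ds <- gintervals("chr1", c(100, 150), c(200, 250), c("+", "-"))
  got <- merge_bidirectional(ds)
  expect_equal(nrow(got), 1)
  expect_equal(got$tags[[1]]$pattern, "overlap")
  expect_equal(got$start, 100)
  expect_equal(got$end, 250)
  div <- gintervals("chr1", c(500, 650), c(600, 750), c("-", "+"))
  got2 <- merge_bidirectional(div, max_distance = 100)
  expect_equal(got2$tags[[1]]$pattern, "divergent")
  expect_equal(nrow(merge_bidirectional(div, max_distance = 10)), 0)
  same <- gintervals("chr1", c(1, 5), c(10, 20), "+")
  expect_equal(nrow(merge_bidirectional(same)), 0)
})
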