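test_that("construction enforces the interval invariants", {
  expect_error(gintervals("chr1", 10, 10), "start >= end")
  expect_error(gintervals("chr1", -5, 10), "negative")
  expect_error(gintervals("chr1", 10, 20, strand = "x"), "strand")
  expect_error(gintervals("chr1", 10, 100, exon_starts = list(c(10, 40)),
                          exon_ends = list(c(50, 60))),
               "sorted and non-overlapping")
  expect_error(gintervals("chr1", 10, 100, exon_starts = list(5),
                          exon_ends = list(20)), "outside footprint")
  x <- gintervals("chr1", 10, 100, exon_starts = list(c(10, 60)),
                  exon_ends = list(c(30, 100)))
  expect_equal(iv_size(x), 60)  # spliced, not end - start
})

test_that("overlap honours half-open bounds, strands and exon structure", {
  a <- gintervals("chr1", 100, 200, "+")
  expect_true(iv_overlaps(a, gintervals("chr1", 199, 300, "+")))
  expect_false(iv_overlaps(a, gintervals("chr1", 200, 300, "+")))
  expect_false(iv_overlaps(a, gintervals("chr2", 100, 200, "+")))
  b <- gintervals("chr1", 150, 250, "-")
  expect_true(iv_overlaps(a, b))
  expect_false(iv_overlaps(a, b, strand_specific = TRUE))
  expect_true(iv_overlaps(a, gintervals("chr1", 150, 250, "*"),
                          strand_specific = TRUE))
  # spliced record whose intron spans the query
  spliced <- gintervals("chr1", 0, 100, exon_starts = list(c(0, 90)),
                        exon_ends = list(c(10, 100)))
  mid <- gintervals("chr1", 40, 60)
  expect_true(iv_overlaps(spliced, mid))
  expect_false(iv_overlaps(spliced, mid, exon_aware = TRUE))
})

test_that("extend is strand-relative and clips at the origin", {
  plus <- gintervals("chr1", 1000, 2000, "+")
  minus <- gintervals("chr1", 1000, 2000, "-")
  expect_equal(iv_extend(plus, upstream = 500)$start, 500)
  expect_equal(iv_extend(plus, upstream = 500)$end, 2000)
  expect_equal(iv_extend(minus, upstream = 500)$end, 2500)
  expect_equal(iv_extend(minus, upstream = 500)$start, 1000)
  expect_equal(iv_extend(gintervals("chr1", 100, 200, "+"),
                         upstream = 500)$start, 0)
  same <- iv_extend(plus, 0, 0)
  expect_equal(same$start, plus$start)
  expect_equal(same$end, plus$end)
})

test_that("distance counts the gap bases and is NA across chromosomes", {
  expect_equal(iv_distance(gintervals("chr1", 150, 160),
                           gintervals("chr1", 200, 300)), 40)
  expect_equal(iv_distance(gintervals("chr1", 100, 200),
                           gintervals("chr1", 150, 250)), 0)
  expect_true(is.na(iv_distance(gintervals("chr1", 1, 10),
                                gintervals("chr2", 1, 10))))
})

test_that("overlap and distance agree with the per-base oracle", {
  set.seed(421)
  n <- 10000
  s1 <- sample.int(400, n, replace = TRUE)
  e1 <- s1 + sample.int(60, n, replace = TRUE)
  s2 <- sample.int(400, n, replace = TRUE)
  e2 <- s2 + sample.int(60, n, replace = TRUE)
  a <- gintervals("chr1", s1, e1)
  b <- gintervals("chr1", s2, e2)
  got_ov <- iv_overlaps(a, b)
  got_d <- iv_distance(a, b)
  exp_ov <- mapply(oracle_overlap_bases, s1, e1, s2, e2)
  exp_d <- mapply(oracle_distance_bases, s1, e1, s2, e2)
  expect_identical(got_ov, unname(exp_ov))
  expect_equal(got_d, unname(exp_d))
  # symmetry and the distance==0 <=> overlaps correspondence
  # (book-ended pairs are the one case with gap 0 but no shared base)
  book_ended <- e1 == s2 | e2 == s1
  expect_identical(got_ov, iv_overlaps(b, a))
  expect_equal(got_d, iv_distance(b, a))
  expect_identical(got_d == 0 & !book_ended, got_ov)
})
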