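test_that("read-information histograms count what they claim", {
  reads <- gintervals("chr1", c(0, 100, 200), c(28, 128, 230), "+")
  h <- size_distribution(reads)
  expect_equal(h$bin_labels, c(28, 30))
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$total, 3)
  expect_equal(size_distribution(gintervals_empty())$total, 0)
  tagged <- gintervals("chr1", c(0, 10), c(5, 15), "+",
                       tags = list(list(copies = 3), NULL))
  hc <- copies_distribution(tagged)
  expect_equal(hc$bin_labels, c(1, 3))  # missing copies tag counts as 1
  expect_equal(hc$counts, c(1, 1))
  spliced <- gintervals("chr1", 0, 100, exon_starts = list(c(0, 50)),
                        exon_ends = list(c(20, 100)))
  he <- exons_distribution(rbind(spliced, gintervals("chr1", 0, 10)))
  expect_equal(he$bin_labels, c(1, 2))
  cl <- clusterize(gintervals("chr1", c(1, 2, 50), c(10, 12, 60), "+"))
  hn <- exons_distribution(cl)
  expect_equal(hn$total, nrow(cl))  # conservation over clusters
})

test_that("nucleotide composition normalizes globally and per position", {
  comp <- nucleotide_composition("AACG")
  expect_equal(unname(comp[c("A", "C", "G", "T")]), c(0.5, 0.25, 0.25, 0))
  pp <- nucleotide_composition(c("AA", "AC"), per_position = TRUE)
  expect_equal(unname(pp[1, "A"]), 1.0)
  expect_equal(unname(pp[2, c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(pp)), c(1, 1))
  expect_equal(unname(nucleotide_composition("AUG")["T"]), 1 / 3)  # U -> T
  expect_error(nucleotide_composition("ACGX"), "non-IUPAC")
})

test_that("density tiles assign by footprint midpoint", {
  expect_equal(density_profile(gintervals("chr1", 0, 10), 100)$chr1$counts, 1)
  # midpoint exactly on a tile boundary goes to the right tile:
  # [96, 106) has midpoint floor((96+105)/2) = 100 -> tile 1
  h <- density_profile(gintervals("chr1", 96, 106), 100)$chr1
  expect_equal(h$bin_labels, c(0, 100))
  expect_equal(h$counts, c(0, 1))
  set.seed(61)
  x <- df_to_gintervals(random_intervals_df(500, n_chroms = 2))
  prof <- density_profile(x, 50000)
  expect_equal(sum(vapply(prof, `[[`, numeric(1), "total")), nrow(x))
})

test_that("distance distribution signs and nearest choice are correct", {
  refs <- gintervals("chr1", 200, 300, "+", "ref1")
  h <- distance_distribution(gintervals("chr1", 150, 160), refs,
                             strand_relative = TRUE)
  expect_equal(attr(h, "distances"), -40)  # query 5' of a + reference
  h2 <- distance_distribution(gintervals("chr1", 150, 160),
                              gintervals("chr1", 200, 300, "-"),
                              strand_relative = TRUE)
  expect_equal(attr(h2, "distances"), 40)  # same side is 3' of a - reference
  expect_equal(attr(distance_distribution(gintervals("chr1", 250, 260),
                                          refs), "distances"), 0)
  far <- distance_distribution(gintervals("chr1", 0, 10), refs,
                               max_distance = 50)
  expect_equal(far$skipped, 1)
  expect_equal(far$total, 0)
  # nearest-reference choice equals a linear-scan oracle
  set.seed(77)
  queries <- df_to_gintervals(random_intervals_df(500, n_chroms = 2,
                                                  max_len = 100))
  references <- df_to_gintervals(random_intervals_df(50, n_chroms = 3,
                                                     max_len = 1000))
  got <- attr(distance_distribution(queries, references), "distances")
  for (i in seq_len(nrow(queries))) {
    same <- references[references$chrom == queries$chrom[i]]
    want <- if (nrow(same) == 0) NA_real_ else
      min(iv_distance(queries[i], same), na.rm = TRUE)
    expect_equal(got[i], want, info = i)
  }
})

test_that("anchor profiles are strand-oriented and find planted peaks", {
  # uniform coverage over a feature body gives a flat metagene
  feat <- gintervals("chr1", 1000, 2000, "+", "g1")
  cover <- gintervals("chr1", rep(seq(1000, 1990, 10), 2),
                      rep(seq(1010, 2000, 10), 2), "+")
  pr <- anchor_profile(cover, feat, "metagene", n_bins = 10)
  expect_equal(pr$mean_signal, rep(2, 10))
  # a minus-strand feature yields the reversed profile
  ramp <- gintervals("chr1", 1000:1499, 1001:1500, "+")  # depth only 5' half
  plus <- anchor_profile(ramp, feat, "metagene", n_bins = 10)
  minus <- anchor_profile(ramp, gintervals("chr1", 1000, 2000, "-", "g1"),
                          "metagene", n_bins = 10)
  expect_equal(minus$mean_signal, rev(plus$mean_signal))
  # planted nucleosome-like peak 100 nt downstream of every TSS
  set.seed(9)
  tss_feats <- gintervals("chr1", seq(10000, 90000, 10000),
                          seq(10000, 90000, 10000) + 3000,
                          rep(c("+", "-"), length.out = 9),
                          sprintf("f%d", 1:9))
  anchors <- ifelse(tss_feats$strand == "+", tss_feats$start,
                    tss_feats$end - 1)
  dirn <- ifelse(tss_feats$strand == "+", 1, -1)
  peak_reads <- do.call(rbind, lapply(seq_len(9), function(i) {
    centers <- anchors[i] + dirn[i] * 100 + sample(-20:20, 60, replace = TRUE)
    gintervals("chr1", centers - 15, centers + 15, tss_feats$strand[i])
  }))
  pr2 <- anchor_profile(peak_reads, tss_feats, "tss", flank = 500)
  expect_lt(abs(pr2$offsets[which.max(pr2$mean_signal)] - 100), 40)
  # short features are skipped and tallied in metagene mode
  shorty <- rbind(feat, gintervals("chr1", 5000, 5005, "+", "tiny"))
  pr3 <- anchor_profile(cover, shorty, "metagene", n_bins = 100)
  expect_equal(pr3$skipped, 1)
})

test_that("plots always write their numeric table as CSV", {
  h <- size_distribution(gintervals("chr1", c(0, 10), c(28, 40), "+"))
  png <- tempfile(fileext = ".png")
  csv <- render_plot(h, png)
  expect_true(file.exists(png))
  tab <- data.table::fread(csv)
  expect_equal(nrow(tab), length(h$bin_labels))
  expect_equal(tab$count, h$counts)
  expect_error(render_plot(ghistogram(numeric(0), numeric(0)),
                           tempfile(fileext = ".png")), "empty")
})
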