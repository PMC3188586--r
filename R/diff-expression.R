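#' Count reads overlapping each region
#'
#' A read increments every region it overlaps by at least one nucleotide
#' (footprint overlap), so counts can sum to more than the read total when
#' regions overlap.  The library total (number of input reads) is attached
#' as attribute `"total"`.
#'
#' @param reads,regions `gintervals`; regions must have distinct names.
#' @param strand_specific require compatible strands.
#' @return named numeric vector of per-region counts.
#' @export
count_reads_per_region <- function(reads, regions, strand_specific = FALSE) {
  if (anyDuplicated(regions$name[!is.na(regions$name)]))
    stop("regions must be distinct by name")
  counts <- numeric(nrow(regions))
  st <- interval_store()
  store_insert(st, reads)
  for (i in seq_len(nrow(regions))) {
    cand <- store_query(st, regions$chrom[i], regions$start[i],
                        regions$end[i])
    if (strand_specific && nrow(cand) > 0L)
      cand <- cand[strands_compatible(cand$strand, regions$strand[i])]
    counts[i] <- nrow(cand)
  }
  names(counts) <- regions$name
  setattr(counts, "total", nrow(reads))
  counts
}

#' Build a two-condition count table
#'
#' @param regions a `gintervals` of reference regions (genes, transposable
#'   elements, clusters, ...), distinct by name.
#' @param counts_a,counts_b per-region counts (raw or normalized).
#' @param total_a,total_b library totals.
#' @return a `count_table` object.
#' @export
count_table <- function(regions, counts_a, counts_b,
                        total_a = sum(counts_a), total_b = sum(counts_b)) {
  stopifnot(length(counts_a) == nrow(regions),
            length(counts_b) == nrow(regions),
            all(counts_a >= 0), all(counts_b >= 0))
  structure(list(regions = regions, counts_a = as.numeric(counts_a),
                 counts_b = as.numeric(counts_b),
                 total_a = as.numeric(total_a),
                 total_b = as.numeric(total_b)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table: %d regions; totals %.6g / %.6g>\n",
              nrow(x$regions), x$total_a, x$total_b))
  invisible(x)
}

#' Count reads per region for two conditions
#'
#' @param reads_a,reads_b `gintervals` of mapped reads per condition.
#' @param regions reference regions.
#' @param strand_specific require compatible strands.
#' @return a [count_table()].
#' @export
build_count_table <- function(reads_a, reads_b, regions,
                              strand_specific = FALSE) {
  ca <- count_reads_per_region(reads_a, regions, strand_specific)
  cb <- count_reads_per_region(reads_b, regions, strand_specific)
  count_table(regions, ca, cb, attr(ca, "total"), attr(cb, "total"))
}

#' Mean-of-totals library-size normalization
#'
#' The simplest scheme: both libraries are scaled to the average of the two
#' library totals, `T = (total_a + total_b) / 2`, i.e. counts in A are
#' multiplied by `T / total_a` and counts in B by `T / total_b`.
#'
#' @param tab a [count_table()] with positive totals.
#' @return normalized `count_table` (equal totals).
#' @export
normalize_mean <- function(tab) {
  if (tab$total_a <= 0 || tab$total_b <= 0) stop("zero library total")
  target <- (tab$total_a + tab$total_b) / 2
  count_table(tab$regions, tab$counts_a * target / tab$total_a,
              tab$counts_b * target / tab$total_b, target, target)
}

#' Indices of the interquartile set
#'
#' Regions ranked by `(counts_a + counts_b) / 2` ascending; the IQR set is
#' 0-based ranks `floor(n/4) <= i < floor(3n/4)`.
#' @param counts_a,counts_b count vectors.
#' @return integer indices into the original order.
#' @keywords internal
iqr_set <- function(counts_a, counts_b) {
  n <- length(counts_a)
  ord <- order((counts_a + counts_b) / 2)
  lo <- floor(n / 4)          # 0-based rank bounds
  hi <- floor(3 * n / 4) - 1
  ord[(lo + 1):(hi + 1)]
}

#' Interquartile normalization
#'
#' Assumes that moderately expressed regions are not differentially
#' expressed: regions are sorted by their average count over the two
#' conditions, and condition B is rescaled so that the regions in the
#' interquartile range carry the same total count in both conditions.
#'
#' @param tab a [count_table()] with at least 4 regions.
#' @return normalized `count_table` (B scaled by `S_A / S_B` over the IQR
#'   set; A unchanged).
#' @export
normalize_interquartile <- function(tab) {
  if (length(tab$counts_a) < 4L) stop("interquartile normalization needs >= 4 regions")
  idx <- iqr_set(tab$counts_a, tab$counts_b)
  sa <- sum(tab$counts_a[idx]); sb <- sum(tab$counts_b[idx])
  if (sb == 0) stop("degenerate library: IQR sum of condition B is zero")
  f <- sa / sb
  count_table(tab$regions, tab$counts_a, tab$counts_b * f,
              tab$total_a, tab$total_b * f)
}

#' Sliding-window averaged counts (length-bias correction)
#'
#' Long regions match more reads and therefore reach significance more
#' easily in count-based tests.  This scheme sets the window width `w` to
#' the spliced size of the smallest region, slides the window along each
#' region's footprint in 1-nt steps (`L - w + 1` placements for footprint
#' length `L`; a single placement when `L <= w`), counts the reads
#' overlapping each placement, and replaces the region's raw count with the
#' mean over placements (fractional).  Library totals remain the read
#' totals.  The per-region mean is computed in closed form from each read's
#' number of overlapping placements, so cost is linear in the read count.
#'
#' @param reads_a,reads_b mapped reads per condition.
#' @param regions reference regions.
#' @return a [count_table()] with fractional window-averaged counts.
#' @export
window_averaged_counts <- function(reads_a, reads_b, regions) {
  stopifnot(nrow(regions) >= 1L)
  w <- min(iv_size(regions))
  ca <- window_mean_counts(reads_a, regions, w)
  cb <- window_mean_counts(reads_b, regions, w)
  count_table(regions, ca, cb, nrow(reads_a), nrow(reads_b))
}

window_mean_counts <- function(reads, regions, w) {
  st <- interval_store()
  store_insert(st, reads)
  vapply(seq_len(nrow(regions)), function(i) {
    rs <- regions$start[i]; re <- regions$end[i]
    len <- re - rs
    if (len <= w) {
      # single placement: plain overlap count
      return(as.numeric(nrow(store_query(st, regions$chrom[i], rs, re))))
    }
    last <- re - w                     # last placement start
    n_place <- len - w + 1
    cand <- store_query(st, regions$chrom[i], rs, re)
    if (nrow(cand) == 0L) return(0)
    # placements s in [rs, last] overlapping read r: s < r.end and s+w > r.start
    lo <- pmax(rs, cand$start - w + 1)
    hi <- pmin(last, cand$end - 1)
    sum(pmax(0, hi - lo + 1)) / n_place
  }, numeric(1))
}

#' Two-sided Fisher exact test on a 2x2 read-count table
#'
#' Given a region's counts `a`, `b` in the two conditions and the remaining
#' library counts `rest_a = total_a - a`, `rest_b = total_b - b`, computes
#' the exact hypergeometric p-value with all margins fixed.  The two-sided
#' p-value sums the probabilities of every table at most as probable as the
#' observed one (with a 1e-7 relative tolerance on the equality, the usual
#' guard against floating-point ties).  Fractional normalized counts must be
#' rounded to integers first (see [round_half_even()]).
#'
#' @param a,b region read counts per condition (non-negative integers).
#' @param rest_a,rest_b library remainders per condition.
#' @param alternative `"two.sided"` (default), `"greater"` (region enriched
#'   in condition A) or `"less"`.
#' @return p-value in `[0, 1]`; degenerate margins give 1.
#' @export
fisher_exact <- function(a, b, rest_a, rest_b,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, rest_a >= 0, rest_b >= 0,
            a == round(a), b == round(b),
            rest_a == round(rest_a), rest_b == round(rest_b))
  m <- a + b               # region row total
  n <- rest_a + rest_b     # remainder row total
  k <- a + rest_a          # condition-A column total
  if (m == 0 || n == 0 || k == 0 || b + rest_b == 0) return(1)
  support <- max(0, k - n):min(k, m)
  if (alternative == "greater")
    return(min(1, stats::phyper(a - 1, m, n, k, lower.tail = FALSE)))
  if (alternative == "less")
    return(min(1, stats::phyper(a, m, n, k)))
  p_obs <- stats::dhyper(a, m, n, k)
  p_all <- stats::dhyper(support, m, n, k)
  take <- p_all <= p_obs * (1 + 1e-7)
  if (all(take)) return(1)  # whole support included, e.g. symmetric tables
  min(1, sum(p_all[take]))
}

#' Round half to even
#'
#' Banker's rounding used to turn fractional normalized counts into the
#' integers the exact test needs (base R's `round()` already implements
#' IEEE half-to-even; this wrapper names the contract).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_even <- function(x) round(x)

#' Benjamini-Hochberg FDR filter
#'
#' Adds `q` (step-up adjusted p-values) and `significant` (`q <= alpha`)
#' columns; the input row order is preserved.
#'
#' @param records a `data.frame`/`data.table` with a `p` column.
#' @param alpha FDR level in (0, 1).
#' @return the records with `q` and `significant` columns.
#' @export
fdr_filter <- function(records, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  records <- as.data.table(copy(records))
  records[, q := stats::p.adjust(p, method = "BH")]
  records[, significant := q <= alpha]
  records[]
}

#' Two-condition differential expression by Fisher exact test
#'
#' For each reference region the reads of both conditions are counted, the
#' chosen normalization applied, the (rounded) counts tested against the
#' library remainders with [fisher_exact()], and the p-values adjusted by
#' Benjamini-Hochberg.
#'
#' @param reads_a,reads_b mapped reads per condition.
#' @param regions reference regions (genes, transposable elements,
#'   clusters, ...), distinct by name.
#' @param normalization `"mean"` (default), `"interquartile"` or `"window"`.
#' @param alpha FDR level.
#' @param strand_specific strand-specific counting.
#' @return a `data.table`: region name, coordinates, counts (normalized),
#'   `p`, `q`, `significant`.
#' @export
diff_expr <- function(reads_a, reads_b, regions,
                      normalization = c("mean", "interquartile", "window"),
                      alpha = 0.05, strand_specific = FALSE) {
  normalization <- match.arg(normalization)
  tab <- if (normalization == "window") {
    # window counting replaces the per-region count; the two libraries
    # still need depth equalization before the exact test can compare them
    normalize_mean(window_averaged_counts(reads_a, reads_b, regions))
  } else {
    build_count_table(reads_a, reads_b, regions, strand_specific)
  }
  if (normalization == "mean") tab <- normalize_mean(tab)
  if (normalization == "interquartile") tab <- normalize_interquartile(tab)
  diff_expr_from_table(tab, alpha = alpha)
}

#' Differential expression from an existing count table
#'
#' @param tab a [count_table()] (already normalized if desired).
#' @param alpha FDR level.
#' @return a `data.table` of per-region test results.
#' @export
diff_expr_from_table <- function(tab, alpha = 0.05) {
  a <- round_half_even(tab$counts_a)
  b <- round_half_even(tab$counts_b)
  ta <- round_half_even(tab$total_a)
  tb <- round_half_even(tab$total_b)
  rest_a <- pmax(0, ta - a)
  rest_b <- pmax(0, tb - b)
  p <- vapply(seq_along(a), function(i)
    fisher_exact(a[i], b[i], rest_a[i], rest_b[i]), numeric(1))
  out <- data.table(name = tab$regions$name, chrom = tab$regions$chrom,
                    start = tab$regions$start, end = tab$regions$end,
                    strand = tab$regions$strand,
                    count_a = tab$counts_a, count_b = tab$counts_b, p = p)
  fdr_filter(out, alpha)
}
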