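# Independent brute-force oracles and randomized-instance generators used
# across the suite.  Each oracle deliberately avoids the code path it checks.

# per-base set-intersection overlap oracle
oracle_overlap_bases <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1))) > 0
}

# gap distance by base enumeration (same chromosome assumed)
oracle_distance_bases <- function(s1, e1, s2, e2) {
  if (oracle_overlap_bases(s1, e1, s2, e2)) return(0)
  b1 <- seq(s1, e1 - 1); b2 <- seq(s2, e2 - 1)
  if (max(b1) < min(b2)) min(b2) - max(b1) - 1 else min(b1) - max(b2) - 1
}

# linear-scan overlap query over a plain data.frame of intervals
oracle_query <- function(df, chrom, qs, qe) {
  hit <- df$chrom == chrom & df$start < qe & df$end > qs
  out <- df[hit, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

# exact two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities via log-factorials (no dhyper)
oracle_fisher <- function(a, b, rest_a, rest_b) {
  r1 <- a + b; r2 <- rest_a + rest_b
  c1 <- a + rest_a; c2 <- b + rest_b
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- function(x) {
    lgamma(r1 + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) +
      lgamma(r2 + 1) - lgamma(c1 - x + 1) - lgamma(r2 - (c1 - x) + 1) -
      (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(c2 + 1))
  }
  lp <- vapply(support, logp, numeric(1))
  p <- exp(lp)
  min(1, sum(p[p <= exp(logp(a)) * (1 + 1e-7)]))
}

# O(n^2) union-find single-linkage clustering oracle
oracle_cluster <- function(df, max_distance, strand_specific) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  joinable <- function(i, j) {
    if (df$chrom[i] != df$chrom[j]) return(FALSE)
    if (strand_specific && df$strand[i] != df$strand[j]) return(FALSE)
    overlap <- df$start[i] < df$end[j] & df$start[j] < df$end[i]
    if (overlap) return(TRUE)
    if (max_distance == 0) return(FALSE)
    gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
    gap <= max_distance
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (joinable(i, j)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sp <- split(seq_len(n), root)
  out <- lapply(sp, function(idx)
    list(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
         end = max(df$end[idx]), n = length(idx)))
  out <- out[order(vapply(out, `[[`, character(1), "chrom"),
                   vapply(out, `[[`, numeric(1), "start"))]
  out
}

random_intervals_df <- function(n, n_chroms = 3, max_coord = 1e6,
                                max_len = 5000) {
  starts <- sample.int(max_coord, n, replace = TRUE)
  lens <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
             start = starts, end = starts + lens,
             strand = sample(c("+", "-", "*"), n, replace = TRUE),
             name = sprintf("iv%06d", seq_len(n)),
             stringsAsFactors = FALSE)
}

df_to_gintervals <- function(df, tags = NULL) {
  gintervals(df$chrom, df$start, df$end, df$strand, df$name, tags = tags)
}

# random multi-exon records for round-trip tests
random_multiexon <- function(n, max_coord = 1e5) {
  recs_es <- vector("list", n); recs_ee <- vector("list", n)
  start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    k <- sample(1:4, 1)
    s0 <- sample.int(max_coord, 1)
    es <- ee <- numeric(k)
    pos <- s0
    for (j in seq_len(k)) {
      es[j] <- pos
      ee[j] <- pos + sample(10:200, 1)
      pos <- ee[j] + sample(20:500, 1)
    }
    start[i] <- es[1]; end[i] <- ee[k]
    if (k > 1) { recs_es[[i]] <- es; recs_ee[[i]] <- ee }
  }
  gintervals(sample(c("chr1", "chr2"), n, replace = TRUE), start, end,
             sample(c("+", "-"), n, replace = TRUE),
             sprintf("rec%05d", seq_len(n)),
             exon_starts = recs_es, exon_ends = recs_ee)
}

# canonical per-record representation for set comparison across formats
canonical_records <- function(x) {
  rep_one <- function(i) {
    e <- iv_exons(x, i)
    sprintf("%s:%s:%s:[%s]", x$chrom[i], x$strand[i], x$name[i],
            paste(sprintf("%d-%d", as.integer(e$starts),
                          as.integer(e$ends)), collapse = ","))
  }
  sort(vapply(seq_len(nrow(x)), rep_one, character(1)))
}
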