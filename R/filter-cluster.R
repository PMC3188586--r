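#' Keep reads within an inclusive spliced-size range
#'
#' Size is the spliced length (sum of exon lengths), so the filter acts on
#' the sequenced read length even for intron-spanning alignments.  The
#' canonical use is the piRNA window, 28 to 30 nt.
#'
#' @param x a `gintervals`.
#' @param min_size,max_size inclusive bounds (nt).
#' @return the filtered `gintervals`, input order preserved.
#' @export
filter_by_size <- function(x, min_size = 0, max_size = Inf) {
  if (min_size > max_size) stop("min_size > max_size")
  if (nrow(x) == 0L) return(x)
  sz <- iv_size(x)
  x[sz >= min_size & sz <= max_size]
}

#' Filter reads on hit-count and mismatch tags
#'
#' Keeps reads satisfying every present constraint.  `exact_hits = 1`
#' selects unique mappers.  A read lacking a tag that a constraint needs is
#' dropped; the number of such reads is attached as attribute
#' `"dropped_missing_tag"`.
#'
#' @param x a `gintervals` carrying `nbOccurrences`/`nbMismatches` tags.
#' @param exact_hits keep reads with exactly this hit count.
#' @param min_hits,max_hits inclusive hit-count bounds.
#' @param max_mismatches maximum number of mismatches.
#' @return filtered `gintervals` with a drop tally attribute.
#' @export
filter_by_tags <- function(x, exact_hits = NULL, min_hits = NULL,
                           max_hits = NULL, max_mismatches = NULL) {
  if (nrow(x) == 0L) {
    setattr(x, "dropped_missing_tag", 0L)
    return(x)
  }
  keep <- rep(TRUE, nrow(x))
  missing_tag <- rep(FALSE, nrow(x))
  need_hits <- !is.null(exact_hits) || !is.null(min_hits) || !is.null(max_hits)
  if (need_hits) {
    h <- iv_tag(x, "nbOccurrences", NA_real_)
    missing_tag <- missing_tag | is.na(h)
    if (!is.null(exact_hits)) keep <- keep & !is.na(h) & h == exact_hits
    if (!is.null(min_hits)) keep <- keep & !is.na(h) & h >= min_hits
    if (!is.null(max_hits)) keep <- keep & !is.na(h) & h <= max_hits
  }
  if (!is.null(max_mismatches)) {
    m <- iv_tag(x, "nbMismatches", NA_real_)
    missing_tag <- missing_tag | is.na(m)
    keep <- keep & !is.na(m) & m <= max_mismatches
  }
  out <- x[keep]
  setattr(out, "dropped_missing_tag", sum(missing_tag & !keep))
  out
}

#' Select or exclude reads by overlap with a reference set
#'
#' Each reference is first widened by the strand-relative flanks (so e.g. an
#' upstream flank captures promoter-derived reads), then each query is kept
#' (mode `"keep"`) if it overlaps at least one extended reference by
#' `min_overlap` nucleotides, or the complement is returned (mode
#' `"exclude"`).  Kept queries gain an `overlapping_refs` tag listing the
#' names of the references they hit.
#'
#' @param queries a `gintervals` of reads.
#' @param references a `gintervals` or an [interval_store()] of annotations.
#' @param mode `"keep"` or `"exclude"`.
#' @param strand_specific require compatible strands.
#' @param upstream,downstream flank widths applied to the references (nt).
#' @param min_overlap minimum shared nucleotides (default 1).
#' @return the selected subset of `queries`.
#' @export
select_by_overlap <- function(queries, references, mode = c("keep", "exclude"),
                              strand_specific = FALSE, upstream = 0,
                              downstream = 0, min_overlap = 1) {
  mode <- match.arg(mode)
  if (inherits(references, "interval_store")) {
    refs <- rows_to_gintervals(store_consolidate(references))
  } else refs <- references
  refs <- iv_extend(refs, upstream, downstream)
  st <- interval_store()
  store_insert(st, refs)
  n <- nrow(queries)
  hit <- logical(n)
  hit_names <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- store_query(st, queries$chrom[i], queries$start[i],
                        queries$end[i])
    if (nrow(cand) == 0L) next
    ov <- pmin(cand$end, queries$end[i]) - pmax(cand$start, queries$start[i])
    ok <- ov >= min_overlap
    if (strand_specific)
      ok <- ok & strands_compatible(cand$strand, queries$strand[i])
    if (any(ok)) {
      hit[i] <- TRUE
      hit_names[[i]] <- cand$name[ok]
    }
  }
  if (mode == "keep") {
    out <- queries[hit]
    if (nrow(out) > 0L) {
      nm <- vapply(hit_names[hit], paste, character(1), collapse = ",")
      out <- iv_set_tag(out, "overlapping_refs", nm)
    }
    out
  } else {
    queries[!hit]
  }
}

#' Merge reads into clusters by single linkage
#'
#' Per chromosome (and per strand unless disabled — small-RNA clusters are
#' strand-coherent loci, so strand-specific merging is the default), reads
#' sorted by start are merged into a growing cluster while the gap to the
#' cluster footprint is at most `max_distance`.  With `max_distance = 0` a
#' read must share at least one nucleotide (book-ended records stay apart,
#' consistent with half-open semantics); a positive `max_distance` also
#' bridges gaps up to that many nucleotides.
#'
#' The result is a `gintervals` with extra columns `n_elements` (member
#' count), `member_names` (list) and `has_unique_mapper` (`TRUE` iff at
#' least one member has hit count `nbOccurrences == 1`), sorted by
#' `(chrom, start)`.
#'
#' @param x a `gintervals` of reads.
#' @param max_distance maximum merged gap (nt), `>= 0`.
#' @param strand_specific merge strands separately (default `TRUE`).
#' @return a cluster table (a `gintervals` with cluster columns).
#' @export
clusterize <- function(x, max_distance = 0, strand_specific = TRUE) {
  stopifnot(max_distance >= 0)
  if (nrow(x) == 0L) {
    out <- copy(x)
    out[, `:=`(n_elements = integer(0), member_names = list(),
               has_unique_mapper = logical(0))]
    return(out)
  }
  d <- data.table(chrom = x$chrom, start = x$start, end = x$end,
                  strand = if (strand_specific) x$strand else "*",
                  name = x$name,
                  unique_mapper = {
                    h <- iv_tag(x, "nbOccurrences", NA_real_)
                    !is.na(h) & h == 1
                  })
  setorder(d, chrom, strand, start, end)
  grp_chr <- paste(d$chrom, d$strand, sep = "\r")
  new_grp <- c(TRUE, grp_chr[-1] != grp_chr[-nrow(d)])
  cmax <- d$end
  cluster_id <- integer(nrow(d))
  cid <- 0L
  run_max <- -Inf
  for (i in seq_len(nrow(d))) {
    breaks <- new_grp[i] ||
      (if (max_distance == 0) d$start[i] >= run_max
       else d$start[i] > run_max + max_distance)
    if (breaks) { cid <- cid + 1L; run_max <- d$end[i] }
    else run_max <- max(run_max, d$end[i])
    cluster_id[i] <- cid
  }
  d[, cid := cluster_id]
  cl <- d[, .(chrom = chrom[1], start = min(start), end = max(end),
              strand = strand[1], n_elements = .N,
              member_names = list(name),
              has_unique_mapper = any(unique_mapper)), by = cid]
  setorder(cl, chrom, start, end)
  out <- gintervals(cl$chrom, cl$start, cl$end, cl$strand,
                    sprintf("cluster_%d", seq_len(nrow(cl))),
                    tags = lapply(cl$n_elements,
                                  function(n) list(nbElements = n)))
  out[, n_elements := cl$n_elements]
  set(out, j = "member_names", value = list(cl$member_names))
  out[, has_unique_mapper := cl$has_unique_mapper]
  out[]
}

#' Filter clusters on member count and unique-mapper content
#'
#' @param clusters output of [clusterize()].
#' @param min_elements minimum member count.
#' @param require_unique_mapper keep only clusters containing at least one
#'   uniquely mapping member (guards loci supported only by multi-mappers).
#' @return filtered cluster table.
#' @export
filter_clusters <- function(clusters, min_elements = 1,
                            require_unique_mapper = FALSE) {
  keep <- clusters$n_elements >= min_elements
  if (require_unique_mapper) keep <- keep & clusters$has_unique_mapper
  clusters[keep]
}

#' Find double-strand and divergent (bidirectional) strand patterns
#'
#' Reads (or clusters) are first merged per strand with [clusterize()];
#' loci are then reported where a `+` cluster and a `-` cluster overlap
#' (`pattern = "overlap"`, double-strand transcription) or where a `-`
#' cluster ends within `max_distance` nucleotides upstream of a `+`
#' cluster's start (`pattern = "divergent"`, the head-to-head layout of a
#' putative bidirectional promoter).  Each reported record spans both
#' contributors; the gap is measured between nearest footprint ends, as in
#' [iv_distance()].
#'
#' @param x a `gintervals` of stranded records.
#' @param max_distance maximum divergent gap (nt).
#' @return a cluster table with a `pattern` tag, possibly empty.
#' @export
merge_bidirectional <- function(x, max_distance = 0) {
  cl <- clusterize(x, max_distance = 0, strand_specific = TRUE)
  plus <- cl[cl$strand == "+"]
  minus <- cl[cl$strand == "-"]
  recs <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$chrom[i] != minus$chrom[j]) next
      pattern <- NULL
      if (plus$start[i] < minus$end[j] && minus$start[j] < plus$end[i]) {
        pattern <- "overlap"
      } else if (minus$end[j] <= plus$start[i] &&
                 plus$start[i] - minus$end[j] <= max_distance) {
        pattern <- "divergent"
      }
      if (is.null(pattern)) next
      recs[[length(recs) + 1L]] <- list(
        chrom = plus$chrom[i],
        start = min(plus$start[i], minus$start[j]),
        end = max(plus$end[i], minus$end[j]),
        n = plus$n_elements[i] + minus$n_elements[j],
        members = c(plus$member_names[[i]], minus$member_names[[j]]),
        uniq = plus$has_unique_mapper[i] || minus$has_unique_mapper[j],
        pattern = pattern)
    }
  }
  if (length(recs) == 0L) {
    out <- gintervals_empty()
    out[, `:=`(n_elements = integer(0), member_names = list(),
               has_unique_mapper = logical(0))]
    return(out)
  }
  out <- gintervals(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    start = vapply(recs, `[[`, numeric(1), "start"),
    end = vapply(recs, `[[`, numeric(1), "end"),
    strand = "*",
    name = sprintf("pattern_%d", seq_along(recs)),
    tags = lapply(recs, function(r) list(pattern = r$pattern,
                                         nbElements = r$n)))
  out[, n_elements := vapply(recs, function(r) as.integer(r$n), integer(1))]
  set(out, j = "member_names", value = list(lapply(recs, `[[`, "members")))
  out[, has_unique_mapper := vapply(recs, `[[`, logical(1), "uniq")]
  setorder(out, chrom, start, end)
  out[]
}
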