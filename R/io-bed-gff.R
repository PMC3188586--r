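## BED and GFF3 bridges.  Parsing and attribute escaping are delegated to
## rtracklayer; this layer only converts between GRanges and the internal
## 0-based half-open gintervals convention and (for GFF3) assembles
## parent/child rows into multi-exon records.

granges_to_gintervals <- function(gr, tags = NULL) {
  n <- length(gr)
  if (n == 0L) return(gintervals_empty())
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "*"
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, n)
  exon_starts <- rep(list(NULL), n); exon_ends <- rep(list(NULL), n)
  if (!is.null(gr$blocks)) {
    bl <- gr$blocks
    for (i in seq_len(n)) {
      if (length(bl[[i]]) > 1L) {
        # blocks are 1-based, relative to the range start
        exon_starts[[i]] <- BiocGenerics::start(gr)[i] - 1 +
          BiocGenerics::start(bl[[i]]) - 1
        exon_ends[[i]] <- BiocGenerics::start(gr)[i] - 1 +
          BiocGenerics::end(bl[[i]])
      }
    }
  }
  gintervals(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
             strand, nm, exon_starts, exon_ends, tags)
}

#' Read a BED file (BED3/BED6/BED12)
#'
#' BED coordinates are already 0-based half-open and pass through unchanged.
#' BED12 blocks expand into exons; a `.` strand becomes unstranded (`*`).
#'
#' @param path BED file.
#' @return a `gintervals`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_gintervals(gr)
}

#' Write intervals as BED (BED6, or BED12 for multi-exon records)
#'
#' @param x a `gintervals`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  multi <- any(!vapply(x$exon_starts, is.null, logical(1)))
  gr <- gintervals_to_granges(x, with_blocks = multi)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

gintervals_to_granges <- function(x, with_blocks = FALSE) {
  n <- nrow(x)
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1, x$end),
    strand = x$strand)
  nm <- x$name
  nm[is.na(nm)] <- "."
  gr$name <- nm
  gr$score <- 0
  if (with_blocks) {
    bl <- vector("list", n)
    for (i in seq_len(n)) {
      e <- iv_exons(x, i)
      bl[[i]] <- IRanges::IRanges(e$starts - x$start[i] + 1,
                                  e$ends - x$start[i])
    }
    gr$blocks <- IRanges::IRangesList(bl)
  }
  gr
}

#' Read a GFF3 annotation file
#'
#' Converts 1-based inclusive GFF3 coordinates to the internal 0-based
#' half-open convention.  Child features sharing a `Parent` are assembled
#' into one multi-exon interval named by the parent ID (footprint and strand
#' from the parent row when present); parentless features yield single-exon
#' intervals.  A child whose parent is never defined triggers a warning and
#' is kept as a standalone interval.  The attribute column is parsed into
#' tags.
#'
#' @param path GFF3 file.
#' @return a `gintervals`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  n <- length(gr)
  if (n == 0L) return(gintervals_empty())
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, n)
  parents <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, n)
  tag_cols <- setdiff(names(mc), c("source", "type", "score", "phase",
                                   "Parent"))
  row_tags <- lapply(seq_len(n), function(i) {
    tg <- list()
    for (cn in tag_cols) {
      v <- mc[[cn]][i]
      if (is(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) == 0L || all(is.na(v))) next
      tg[[cn]] <- if (length(v) == 1L) v else paste(v, collapse = ",")
    }
    if (length(tg)) tg else NULL
  })

  is_child <- !is.na(parents)
  child_of <- split(which(is_child), parents[is_child])
  orphan_parents <- setdiff(names(child_of), ids[!is.na(ids)])
  if (length(orphan_parents) > 0L)
    warning(sprintf("GFF3: %d feature(s) reference undefined Parent(s): %s",
                    sum(is_child & parents %in% orphan_parents),
                    paste(head(orphan_parents, 5), collapse = ", ")))
  has_children <- !is.na(ids) & ids %in% names(child_of)
  # rows emitted standalone: parentless, orphaned children, and intermediate
  # rows that are themselves children with children (nested hierarchies)
  standalone <- which(!has_children &
                        (!is_child | parents %in% orphan_parents))

  recs <- list()
  st <- GenomicRanges::start(gr) - 1
  en <- GenomicRanges::end(gr)
  strnd <- as.character(BiocGenerics::strand(gr))
  chr <- as.character(GenomicRanges::seqnames(gr))
  for (i in standalone) {
    recs[[length(recs) + 1L]] <- list(
      chrom = chr[i], start = st[i], end = en[i], strand = strnd[i],
      name = if (!is.na(ids[i])) ids[i] else NA_character_,
      exon_starts = NULL, exon_ends = NULL, tags = row_tags[[i]])
  }
  for (pid in intersect(names(child_of), ids)) {
    kids <- child_of[[pid]]
    prow <- which(ids == pid)[1]
    ord <- order(st[kids])
    es <- st[kids][ord]; ee <- en[kids][ord]
    recs[[length(recs) + 1L]] <- list(
      chrom = chr[prow], start = min(st[prow], es[1]),
      end = max(en[prow], ee[length(ee)]), strand = strnd[prow],
      name = pid,
      exon_starts = if (length(es) > 1L) es else NULL,
      exon_ends = if (length(ee) > 1L) ee else NULL,
      tags = row_tags[[prow]])
  }
  gintervals(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    start = vapply(recs, `[[`, numeric(1), "start"),
    end = vapply(recs, `[[`, numeric(1), "end"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    name = vapply(recs, `[[`, character(1), "name"),
    exon_starts = lapply(recs, `[[`, "exon_starts"),
    exon_ends = lapply(recs, `[[`, "exon_ends"),
    tags = lapply(recs, `[[`, "tags"))
}

#' Write intervals as GFF3
#'
#' Restores 1-based inclusive coordinates.  Single-exon records become one
#' `match` feature; a multi-exon record becomes a `match` parent plus
#' `match_part` children linked by `Parent` (standard practice for mapped
#' reads).  Scalar tags are written into the attribute column.
#'
#' @param x a `gintervals`.
#' @param path destination file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path, source = "rnatoolbox") {
  n <- nrow(x)
  ids <- x$name
  blank <- is.na(ids) | duplicated(ids)
  ids[blank] <- sprintf("rec%06d", which(blank))
  lines <- c("##gff-version 3")
  for (i in seq_len(n)) {
    attrs <- sprintf("ID=%s", gff3_escape(ids[i]))
    tg <- x$tags[[i]]
    for (k in setdiff(names(tg), c("ID", "Parent"))) {
      v <- tg[[k]]
      if (length(v) == 1L && !is.na(v))
        attrs <- paste0(attrs, ";", gff3_escape(k), "=", gff3_escape(v))
    }
    strand <- if (x$strand[i] == "*") "." else x$strand[i]
    lines <- c(lines, sprintf("%s\t%s\tmatch\t%d\t%d\t.\t%s\t.\t%s",
                              x$chrom[i], source, as.integer(x$start[i] + 1),
                              as.integer(x$end[i]), strand, attrs))
    es <- x$exon_starts[[i]]
    if (!is.null(es) && length(es) > 1L) {
      ee <- x$exon_ends[[i]]
      lines <- c(lines, sprintf(
        "%s\t%s\tmatch_part\t%d\t%d\t.\t%s\t.\tParent=%s",
        x$chrom[i], source, as.integer(es + 1), as.integer(ee), strand,
        gff3_escape(ids[i])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gff3_escape <- function(s) {
  s <- gsub("%", "%25", as.character(s), fixed = TRUE)
  s <- gsub(";", "%3B", s, fixed = TRUE)
  s <- gsub("=", "%3D", s, fixed = TRUE)
  s <- gsub(",", "%2C", s, fixed = TRUE)
  s
}
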