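#' @import data.table
#' @importFrom stats median quantile rbinom rnbinom rpois runif setNames
#' @importFrom utils head tail
#' @importFrom methods is
NULL

#' Construct a table of genomic intervals
#'
#' The central container of the package: a `data.table` with one row per
#' stranded, possibly multi-exon genomic interval.  Coordinates are 0-based
#' half-open `[start, end)` everywhere inside the package; conversion to and
#' from 1-based inclusive conventions happens only in the format readers and
#' writers.
#'
#' Columns:
#' \describe{
#'   \item{chrom}{chromosome name.}
#'   \item{start, end}{footprint bounds, 0-based half-open, `start < end`.}
#'   \item{strand}{one of `"+"`, `"-"`, `"*"` (unstranded).}
#'   \item{name}{record identifier.}
#'   \item{exon_starts, exon_ends}{list columns of parallel numeric vectors
#'     giving the exon sub-intervals (same convention).  A `NULL` entry means
#'     a single exon spanning the footprint.}
#'   \item{tags}{list column of named lists carrying per-record attributes
#'     such as `nbOccurrences` (hit count), `nbMismatches`, `copies`.}
#' }
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors of footprint bounds (0-based half-open).
#' @param strand strand of each record; recycled.
#' @param name record identifiers; recycled, `NA` allowed.
#' @param exon_starts,exon_ends optional lists of exon bound vectors.
#' @param tags optional list of named lists of per-record attributes.
#' @return a `gintervals` object (a keyed-free `data.table`).
#' @examples
#' gintervals("chr1", 100, 200, strand = "+", name = "r1")
#' @export
gintervals <- function(chrom, start, end, strand = "*", name = NA_character_,
                       exon_starts = NULL, exon_ends = NULL, tags = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom  <- rep_len(as.character(chrom), n)
  start  <- rep_len(as.numeric(start), n)
  end    <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  name   <- rep_len(as.character(name), n)
  if (is.null(exon_starts)) exon_starts <- rep(list(NULL), n)
  if (is.null(exon_ends))   exon_ends   <- rep(list(NULL), n)
  if (is.null(tags))        tags        <- rep(list(NULL), n)
  stopifnot(length(exon_starts) == n, length(exon_ends) == n,
            length(tags) == n)
  x <- data.table(chrom = chrom, start = start, end = end, strand = strand,
                  name = name, exon_starts = exon_starts,
                  exon_ends = exon_ends, tags = tags)
  setattr(x, "class", c("gintervals", class(data.table())))
  validate_gintervals(x)
  x
}

#' Validate the gintervals invariants
#'
#' Checks `start < end`, strand alphabet, and that exon lists are sorted,
#' non-overlapping and contained in the footprint.
#'
#' @param x a `gintervals` object.
#' @return `x` invisibly; errors on violation.
#' @export
validate_gintervals <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (any(x$start < 0)) stop("negative start coordinate")
  if (any(x$start >= x$end)) stop("invalid interval: start >= end")
  for (i in seq_len(nrow(x))) {
    es <- x$exon_starts[[i]]; ee <- x$exon_ends[[i]]
    if (is.null(es)) next
    if (length(es) != length(ee)) stop("exon bound lengths differ")
    if (any(es >= ee)) stop("invalid exon: start >= end")
    if (any(es < x$start[i]) || any(ee > x$end[i]))
      stop("exon outside footprint")
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop("exons must be sorted and non-overlapping")
  }
  invisible(x)
}

#' Empty interval table
#' @return a zero-row `gintervals`.
#' @export
gintervals_empty <- function() {
  gintervals(character(0), numeric(0), numeric(0))
}

#' Exon starts/ends of one record with the single-exon default applied
#' @param x a `gintervals`; `i` row index.
#' @return list with numeric `starts` and `ends`.
#' @export
iv_exons <- function(x, i) {
  es <- x$exon_starts[[i]]
  if (is.null(es)) list(starts = x$start[i], ends = x$end[i])
  else list(starts = es, ends = x$exon_ends[[i]])
}

#' Spliced size of each interval
#'
#' The size of a record is the sum of its exon lengths (the sequenced read
#' length for a spliced read), not `end - start`.
#'
#' @param x a `gintervals`.
#' @return numeric vector of sizes.
#' @export
iv_size <- function(x) {
  if (nrow(x) == 0L) return(numeric(0))
  vapply(seq_len(nrow(x)), function(i) {
    e <- iv_exons(x, i)
    sum(e$ends - e$starts)
  }, numeric(1))
}

#' Fetch one tag across records
#' @param x a `gintervals`.
#' @param key tag name, e.g. `"nbOccurrences"`.
#' @param default value used where the tag is absent.
#' @return vector of tag values.
#' @export
iv_tag <- function(x, key, default = NA) {
  vapply(x$tags, function(tg) {
    v <- tg[[key]]
    if (is.null(v)) default else as.vector(v, mode = mode(default))
  }, default)
}

#' Set one tag on every record
#' @param x a `gintervals`.
#' @param key tag name.
#' @param values vector of values, recycled.
#' @return modified copy of `x`.
#' @export
iv_set_tag <- function(x, key, values) {
  x <- copy(x)
  values <- rep_len(values, nrow(x))
  new_tags <- mapply(function(tg, v) {
    if (is.null(tg)) tg <- list()
    tg[[key]] <- v
    tg
  }, x$tags, values, SIMPLIFY = FALSE)
  # set() with a wrapped list: `:=` would unwrap a length-1 list column
  set(x, j = "tags", value = list(new_tags))
  x
}

strands_compatible <- function(sa, sb) sa == sb | sa == "*" | sb == "*"

#' Pairwise overlap test
#'
#' Tests whether intervals overlap by at least one nucleotide in half-open
#' coordinates.  With `exon_aware = TRUE` a pair overlaps only if some exon of
#' one shares a base with some exon of the other; otherwise the footprints
#' `[start, end)` are compared.  Records on different chromosomes never
#' overlap; with `strand_specific = TRUE` strands must be compatible
#' (unstranded `"*"` matches both).
#'
#' @param a,b `gintervals` of equal length (or length 1, recycled).
#' @param strand_specific require compatible strands.
#' @param exon_aware compare exon structure rather than footprints.
#' @return logical vector.
#' @export
iv_overlaps <- function(a, b, strand_specific = FALSE, exon_aware = FALSE) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  out <- a$chrom[ia] == b$chrom[ib] &
    a$start[ia] < b$end[ib] & b$start[ib] < a$end[ia]
  if (strand_specific)
    out <- out & strands_compatible(a$strand[ia], b$strand[ib])
  if (exon_aware && any(out)) {
    for (k in which(out)) {
      ea <- iv_exons(a, ia[k]); eb <- iv_exons(b, ib[k])
      hit <- FALSE
      for (j in seq_along(ea$starts)) {
        if (any(ea$starts[j] < eb$ends & eb$starts < ea$ends[j])) {
          hit <- TRUE; break
        }
      }
      out[k] <- hit
    }
  }
  out
}

#' Extend intervals by strand-relative flanks
#'
#' Widens each footprint by `upstream` nucleotides on the 5' side and
#' `downstream` on the 3' side.  For `-` strand records upstream extends the
#' `end` coordinate.  Unstranded records are treated as `+`.  The start is
#' clipped at 0 and the exon structure is replaced by the single widened
#' footprint.
#'
#' @param x a `gintervals`.
#' @param upstream,downstream non-negative flank widths (nt).
#' @return extended copy of `x`.
#' @export
iv_extend <- function(x, upstream = 0, downstream = 0) {
  stopifnot(upstream >= 0, downstream >= 0)
  minus <- x$strand == "-"
  gintervals(x$chrom,
             pmax(0, x$start - ifelse(minus, downstream, upstream)),
             x$end + ifelse(minus, upstream, downstream),
             x$strand, x$name, tags = x$tags)
}

#' Pairwise gap distance between intervals
#'
#' Returns `NA` when chromosomes differ, 0 when the footprints share at least
#' one base or are book-ended, and otherwise the number of bases strictly
#' between them: `max(start) - min(end)` in half-open coordinates.
#'
#' @param a,b `gintervals` of equal length (or length 1, recycled).
#' @return numeric vector of distances (`NA` = different chromosome).
#' @export
iv_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  d <- pmax(0, pmax(a$start[ia], b$start[ib]) - pmin(a$end[ia], b$end[ib]))
  d[a$chrom[ia] != b$chrom[ib]] <- NA_real_
  d
}
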