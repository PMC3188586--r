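## Nested-bin genome indexing (standard 5-level genome-browser scheme:
## bin sizes 128 kb, 1 Mb, 8 Mb, 64 Mb, 512 Mb; level offsets 585, 73, 9, 1, 0).

BIN_OFFSETS <- c(585, 73, 9, 1, 0)
BIN_SHIFTS  <- c(17, 20, 23, 26, 29)
BIN_COUNTS  <- c(4096, 512, 64, 8, 1)

#' Smallest nested bin containing an interval
#'
#' Maps a half-open interval to the smallest bin that fully contains it in
#' the 5-level nested-bin hierarchy used by genome browsers (128 kb leaf
#' bins).  Intervals reaching beyond 512 Mb fall into the root bin 0 rather
#' than erroring, so unusual scaffolds remain queryable.
#'
#' @param start,end numeric vectors, 0-based half-open, `0 <= start < end`.
#' @return integer vector of bin identifiers.
#' @examples
#' bin_of(0, 1000)        # first 128 kb bin: 585
#' bin_of(131072, 131073) # second 128 kb bin: 586
#' bin_of(0, 2^29)        # root bin: 0
#' @export
bin_of <- function(start, end) {
  n <- max(length(start), length(end))
  start <- rep_len(as.numeric(start), n); end <- rep_len(as.numeric(end), n)
  if (any(start < 0)) stop("invalid interval: negative start")
  if (any(start >= end)) stop("invalid interval: start >= end")
  res <- integer(n)
  done <- logical(n)
  hi <- end - 1
  for (k in seq_along(BIN_OFFSETS)) {
    bs <- start %/% 2^BIN_SHIFTS[k]
    be <- hi %/% 2^BIN_SHIFTS[k]
    hit <- !done & bs == be & be < BIN_COUNTS[k]
    res[hit] <- as.integer(BIN_OFFSETS[k] + bs[hit])
    done <- done | hit
  }
  res  # anything not placed spans beyond the scheme -> root bin 0
}

#' Bins that can hold an interval overlapping a range
#'
#' For a query range, returns every bin whose span can contain an overlapping
#' stored interval: the same-level bins covering the range at each of the 5
#' levels (which together enumerate the query's ancestors and all contained
#' descendants).  Query cost is therefore proportional to the hierarchy depth
#' plus the number of leaf bins the range spans, never to the table size.
#'
#' @param start,end scalar query bounds (0-based half-open).
#' @return integer vector of candidate bin identifiers.
#' @export
bins_for_range <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, start < end)
  start <- max(0, start)
  hi <- end - 1
  out <- integer(0)
  for (k in seq_along(BIN_OFFSETS)) {
    bs <- max(0, start %/% 2^BIN_SHIFTS[k])
    be <- min(BIN_COUNTS[k] - 1, hi %/% 2^BIN_SHIFTS[k])
    if (bs <= be) out <- c(out, as.integer(BIN_OFFSETS[k] + bs:be))
  }
  unique(c(out, 0L))  # root bin also holds beyond-scheme intervals
}

#' Create (or reopen) an indexed interval store
#'
#' A multiset container of genomic intervals supporting overlap-range queries
#' through the nested-bin scheme.  Records live in a table keyed on
#' `(chrom, bin)`, so a query probes only the handful of candidate bins of
#' its range (sublinear point lookups) and then verifies coordinates.  With a
#' `path` the store persists to a single plain-text file on
#' [store_close()]/[store_save()] and reopens from it; `path = NULL` gives a
#' purely in-memory store.
#'
#' @param path optional on-disk location.  If the file exists it is loaded.
#' @return an `interval_store` object.
#' @examples
#' st <- interval_store()
#' store_insert(st, gintervals("chr1", c(1, 50, 200), c(100, 150, 300)))
#' store_query(st, "chr1", 90, 210)
#' @export
interval_store <- function(path = NULL) {
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$dt <- NULL          # consolidated, keyed table
  st$pending <- list()   # unconsolidated insert batches
  st$n_pending <- 0L
  class(st) <- "interval_store"
  if (!is.null(path) && file.exists(path)) store_load_(st, path)
  st
}

#' @export
print.interval_store <- function(x, ...) {
  cat(sprintf("<interval_store: %d records%s>\n", store_count(x),
              if (is.null(x$path)) ", in-memory" else paste0(", ", x$path)))
  invisible(x)
}

encode_exons <- function(starts, ends) {
  if (is.null(starts)) return(NA_character_)
  paste(sprintf("%d-%d", as.integer(starts), as.integer(ends)),
        collapse = ",")
}

decode_exons <- function(s) {
  if (is.na(s)) return(list(NULL, NULL))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  list(vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
       vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

gintervals_to_rows <- function(x) {
  data.table(
    chrom = x$chrom, bin = bin_of(x$start, x$end),
    start = x$start, end = x$end, strand = x$strand, name = x$name,
    exons = mapply(encode_exons, x$exon_starts, x$exon_ends),
    tags = vapply(x$tags, function(tg) {
      if (is.null(tg) || length(tg) == 0L) NA_character_
      else as.character(jsonlite::toJSON(tg, auto_unbox = TRUE))
    }, character(1)))
}

rows_to_gintervals <- function(dt) {
  if (nrow(dt) == 0L) return(gintervals_empty())
  ex <- lapply(dt$exons, decode_exons)
  gintervals(dt$chrom, dt$start, dt$end, dt$strand, dt$name,
             exon_starts = lapply(ex, `[[`, 1),
             exon_ends = lapply(ex, `[[`, 2),
             tags = lapply(dt$tags, function(s) {
               if (is.na(s)) NULL else jsonlite::fromJSON(s, simplifyVector = TRUE)
             }))
}

#' Insert intervals into a store
#' @param store an [interval_store()].
#' @param x a `gintervals` (any number of rows; duplicates are retained).
#' @return the store, invisibly.
#' @export
store_insert <- function(store, x) {
  if (nrow(x) > 0L) {
    store$pending[[length(store$pending) + 1L]] <- gintervals_to_rows(x)
    store$n_pending <- store$n_pending + nrow(x)
  }
  invisible(store)
}

empty_store_dt <- function() {
  data.table(chrom = character(0), bin = integer(0), start = numeric(0),
             end = numeric(0), strand = character(0), name = character(0),
             exons = character(0), tags = character(0))
}

store_consolidate <- function(store) {
  if (store$n_pending > 0L || is.null(store$dt)) {
    store$dt <- rbindlist(c(list(empty_store_dt()), list(store$dt),
                            store$pending))
    setkey(store$dt, chrom, bin)
    store$pending <- list(); store$n_pending <- 0L
  }
  store$dt
}

#' Number of records in a store
#' @param store an [interval_store()].
#' @return integer count.
#' @export
store_count <- function(store) {
  (if (is.null(store$dt)) 0L else nrow(store$dt)) + store$n_pending
}

#' Chromosomes present in a store
#' @param store an [interval_store()].
#' @return character vector.
#' @export
store_chroms <- function(store) unique(store_consolidate(store)$chrom)

#' Overlap-range query
#'
#' Returns every stored interval whose footprint intersects
#' `[start, end)` on `chrom`, in ascending `(start, end)` order.  Only the
#' candidate bins of the range (see [bins_for_range()]) are probed before
#' coordinates are verified.  An unknown chromosome yields an empty result.
#'
#' @param store an [interval_store()].
#' @param chrom chromosome name.
#' @param start,end query bounds (0-based half-open).
#' @param count_probes attach the number of probed bins as attribute
#'   `"bins_probed"` (used to assert sublinear access).
#' @return a `gintervals` of the overlapping records.
#' @export
store_query <- function(store, chrom, start, end, count_probes = FALSE) {
  stopifnot(start < end)
  qc <- chrom; qs <- start; qe <- end
  dt <- store_consolidate(store)
  bins <- bins_for_range(qs, qe)
  hit <- dt[.(qc, bins), nomatch = NULL]
  hit <- hit[start < qe & end > qs]
  setorder(hit, start, end)
  out <- rows_to_gintervals(hit)
  if (count_probes) setattr(out, "bins_probed", length(bins))
  out
}

#' Persist a store to its file
#' @param store an [interval_store()].
#' @param path destination; defaults to the store's own path.
#' @return the store, invisibly.
#' @export
store_save <- function(store, path = store$path) {
  if (is.null(path)) stop("store has no path; pass one explicitly")
  dt <- store_consolidate(store)
  fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(store)
}

store_load_ <- function(store, path) {
  dt <- fread(path, sep = "\t", quote = "", na.strings = "NA",
              colClasses = list(character = c("chrom", "strand", "name",
                                              "exons", "tags")))
  setkey(dt, chrom, bin)
  store$dt <- dt
  invisible(store)
}

#' Flush and close a persistent store
#' @param store an [interval_store()].
#' @return invisibly, `NULL`.
#' @export
store_close <- function(store) {
  if (!is.null(store$path)) store_save(store)
  invisible(NULL)
}
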