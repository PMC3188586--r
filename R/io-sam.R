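#' Read mapped reads from a SAM file
#'
#' Parses plain-text SAM alignments into a `gintervals` table.  Unmapped
#' records (FLAG 0x4 or `*` reference) are skipped; the 1-based POS is
#' converted to the internal 0-based half-open convention.  The CIGAR string
#' is walked to recover exon structure: `M`, `=`, `X` and `D` consume
#' reference within the current exon, `N` closes it (an intron, so spliced
#' long reads keep their exons), and `I`, `S`, `H`, `P` consume no reference.
#' FLAG bit 0x10 sets the `-` strand.  Optional fields are carried as tags
#' with `NH` exposed as `nbOccurrences` (hit count) and `NM` as
#' `nbMismatches`; unrecognized tags are preserved verbatim.
#'
#' @param path SAM file (headers optional).
#' @return a `gintervals` of mapped records, in file order.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) return(gintervals_empty())
  recs <- vector("list", length(lines))
  kept <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop(sprintf("SAM parse error at line %d: fewer than 11 fields", i))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.numeric(f[4]))
    if (is.na(flag) || is.na(pos))
      stop(sprintf("SAM parse error at line %d: non-numeric FLAG/POS", i))
    if (bitwAnd(flag, 4L) != 0L || f[3] == "*") next
    ex <- cigar_to_exons(f[6], pos - 1)
    if (is.null(ex))
      stop(sprintf("SAM parse error at line %d: malformed CIGAR '%s'", i, f[6]))
    tags <- parse_sam_tags(if (length(f) > 11L) f[12:length(f)] else character(0))
    kept <- kept + 1L
    recs[[kept]] <- list(
      chrom = f[3], start = ex$starts[1], end = ex$ends[length(ex$ends)],
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+", name = f[1],
      exon_starts = if (length(ex$starts) > 1L) ex$starts else NULL,
      exon_ends = if (length(ex$ends) > 1L) ex$ends else NULL,
      tags = tags)
  }
  if (kept == 0L) return(gintervals_empty())
  recs <- recs[seq_len(kept)]
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

#' Exons implied by a CIGAR string
#'
#' Walks a CIGAR from a 0-based reference start.  Returns `NULL` on a
#' malformed string, otherwise the exon bounds (half-open).
#'
#' @param cigar CIGAR string, e.g. `"10M50N10M"`.
#' @param start 0-based reference position of the first consumed base.
#' @return list with `starts` and `ends`, or `NULL` if unparsable.
#' @export
cigar_to_exons <- function(cigar, start) {
  if (cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) return(NULL)
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.numeric(sub("[MIDNSHP=X]$", "", m))
  ops <- sub("^[0-9]+", "", m)
  starts <- numeric(0); ends <- numeric(0)
  cur_start <- start; cur <- start
  open <- FALSE
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op %in% c("M", "=", "X", "D")) {
      if (!open) { cur_start <- cur; open <- TRUE }
      cur <- cur + lens[k]
    } else if (op == "N") {
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
      open <- FALSE
      cur <- cur + lens[k]
    }
    # I, S, H, P: no reference consumed
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
  if (length(starts) == 0L) return(NULL)
  list(starts = starts, ends = ends)
}

parse_sam_tags <- function(fields) {
  if (length(fields) == 0L) return(NULL)
  tags <- list()
  for (f in fields) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3L) next
    key <- parts[1]; type <- parts[2]
    val <- paste(parts[-(1:2)], collapse = ":")
    val <- switch(type, i = as.integer(val), f = as.numeric(val), val)
    if (key == "NH") tags$nbOccurrences <- val
    else if (key == "NM") tags$nbMismatches <- val
    else tags[[key]] <- val
  }
  if (length(tags) == 0L) NULL else tags
}

#' Write reads as SAM-like tabular records
#'
#' Emits a minimal SAM representation (QNAME, FLAG, RNAME, POS, MAPQ, CIGAR
#' with `N` gaps between exons, and `NH`/`NM` tags where present).  Sequence
#' and quality are written as `*`.
#'
#' @param x a `gintervals`.
#' @param path destination file.
#' @param chrom_sizes optional named vector used to emit `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, chrom_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(chrom_sizes))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  if (nrow(x) == 0L) return(invisible(path))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    e <- iv_exons(x, i)
    cig <- character(0)
    for (j in seq_along(e$starts)) {
      if (j > 1L)
        cig <- c(cig, sprintf("%dN", as.integer(e$starts[j] - e$ends[j - 1])))
      cig <- c(cig, sprintf("%dM", as.integer(e$ends[j] - e$starts[j])))
    }
    flag <- if (x$strand[i] == "-") 16L else 0L
    extra <- character(0)
    nh <- x$tags[[i]]$nbOccurrences
    nm <- x$tags[[i]]$nbMismatches
    if (!is.null(nh)) extra <- c(extra, sprintf("NH:i:%d", as.integer(nh)))
    if (!is.null(nm)) extra <- c(extra, sprintf("NM:i:%d", as.integer(nm)))
    paste(c(x$name[i], flag, x$chrom[i], as.integer(x$start[i] + 1), 255,
            paste(cig, collapse = ""), "*", 0, 0, "*", "*", extra),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
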