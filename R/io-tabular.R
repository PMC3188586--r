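#' Column specification for generic tabular mapper output
#'
#' Many aligners emit plain tab-separated tables whose columns hold the
#' chromosome, the matched coordinates and (sometimes) a strand or hit
#' count.  A `tabular_spec` names those columns (1-based indices) and the
#' coordinate convention of the dialect, so one reader covers them all.
#'
#' @param chrom,start,end required column indices.
#' @param strand,name,hits optional column indices (`hits` feeds the
#'   `nbOccurrences` tag for dialects that report multiple placements).
#' @param one_based logical; coordinates are 1-based.
#' @param inclusive_end logical; the end coordinate is inclusive.
#' @param reversed_means_minus logical; `start > end` encodes the `-` strand
#'   (BLAST-style), in which case the coordinates are swapped.
#' @param header logical; skip a header line.
#' @return a `tabular_spec` list.
#' @export
tabular_spec <- function(chrom, start, end, strand = NULL, name = NULL,
                         hits = NULL, one_based = TRUE, inclusive_end = TRUE,
                         reversed_means_minus = FALSE, header = FALSE) {
  structure(list(chrom = chrom, start = start, end = end, strand = strand,
                 name = name, hits = hits, one_based = one_based,
                 inclusive_end = inclusive_end,
                 reversed_means_minus = reversed_means_minus,
                 header = header),
            class = "tabular_spec")
}

#' Shipped column-spec presets
#'
#' `"blast8"` covers BLAST `-m 8` tabular output (query, subject, identity,
#' ..., sstart, send): subject coordinates are 1-based inclusive and a
#' reversed pair encodes the minus strand.
#'
#' @param name preset name.
#' @return a [tabular_spec()].
#' @export
tabular_preset <- function(name = c("blast8")) {
  name <- match.arg(name)
  switch(name,
         blast8 = tabular_spec(chrom = 2, start = 9, end = 10, name = 1,
                               one_based = TRUE, inclusive_end = TRUE,
                               reversed_means_minus = TRUE))
}

#' Read a generic tabular mapping file
#'
#' @param path tab-separated file.
#' @param spec a [tabular_spec()] or preset name (see [tabular_preset()]).
#' @return a `gintervals`.
#' @export
read_tabular_mapping <- function(path, spec) {
  if (is.character(spec)) spec <- tabular_preset(spec)
  lines <- readLines(path)
  if (spec$header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gintervals_empty())
  need <- max(unlist(spec[c("chrom", "start", "end", "strand", "name",
                            "hits")]))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < need))
    stop(sprintf("tabular parse error at line %d: %d column(s), need %d",
                 which(nf < need)[1] + spec$header, nf[nf < need][1], need))
  col <- function(j) vapply(rows, `[[`, character(1), j)
  chrom <- col(spec$chrom)
  start <- as.numeric(col(spec$start))
  end <- as.numeric(col(spec$end))
  strand <- rep("+", length(lines))
  if (!is.null(spec$strand)) {
    strand <- col(spec$strand)
    strand[!strand %in% c("+", "-")] <- "*"
  } else if (!spec$reversed_means_minus) {
    strand <- rep("*", length(lines))
  }
  if (spec$reversed_means_minus) {
    rev <- start > end
    strand[rev] <- "-"
    tmp <- start[rev]; start[rev] <- end[rev]; end[rev] <- tmp
  }
  if (spec$one_based) start <- start - 1
  if (spec$inclusive_end == spec$one_based) {
    # nothing: 1-based inclusive or 0-based exclusive both land half-open
  } else if (spec$inclusive_end) {
    end <- end + 1
  } else {
    end <- end - 1  # 1-based exclusive (rare)
  }
  nm <- if (!is.null(spec$name)) col(spec$name) else NA_character_
  tags <- if (!is.null(spec$hits)) {
    lapply(as.integer(col(spec$hits)), function(h) list(nbOccurrences = h))
  } else NULL
  gintervals(chrom, start, end, strand, nm, tags = tags)
}

#' Spreadsheet (CSV) export
#'
#' One row per record with `chrom,start,end,strand,name,size` plus, when
#' present, cluster member counts and scalar tags as extra columns — a
#' diffable file that opens directly in spreadsheet software.
#'
#' @param x a `gintervals` (clusters included).
#' @param path destination `.csv`.
#' @return `path`, invisibly.
#' @export
write_spreadsheet <- function(x, path) {
  out <- data.table(chrom = x$chrom, start = as.integer(x$start),
                    end = as.integer(x$end), strand = x$strand,
                    name = x$name, size = iv_size(x))
  if ("n_elements" %in% names(x)) out$nbElements <- x$n_elements
  keys <- unique(unlist(lapply(x$tags, names)))
  for (k in keys) {
    v <- vapply(x$tags, function(tg) {
      w <- tg[[k]]
      if (is.null(w) || length(w) != 1L) NA_character_ else as.character(w)
    }, character(1))
    out[[k]] <- v
  }
  fwrite(out, path)
  invisible(path)
}

#' Convert between supported interval formats
#'
#' @param infile,outfile paths.
#' @param from,to formats among `"sam"`, `"bed"`, `"gff3"`, `"csv"` (write
#'   only) and `"tabular:<preset>"` (read only).
#' @return `outfile`, invisibly.
#' @export
convert_format <- function(infile, outfile, from, to) {
  x <- read_intervals(infile, from)
  write_intervals(x, outfile, to)
}

#' Read any supported format
#' @param path input file.
#' @param format `"sam"`, `"bed"`, `"gff3"` or `"tabular:<preset>"`.
#' @return a `gintervals`.
#' @export
read_intervals <- function(path, format) {
  if (startsWith(format, "tabular"))
    return(read_tabular_mapping(path, sub("^tabular:?", "", format)))
  switch(tolower(format),
         sam = read_sam(path),
         bed = read_bed(path),
         gff3 = , gff = read_gff3(path),
         stop("unsupported input format: ", format))
}

#' Write any supported format
#' @param x a `gintervals`.
#' @param path output file.
#' @param format `"sam"`, `"bed"`, `"gff3"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format) {
  switch(tolower(format),
         sam = write_sam(x, path),
         bed = write_bed(x, path),
         gff3 = , gff = write_gff3(x, path),
         csv = write_spreadsheet(x, path),
         stop("unsupported output format: ", format))
}
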