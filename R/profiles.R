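#' Histogram container
#'
#' A minimal ordered histogram: bin labels, counts, total, plus an explicit
#' tally of records that were skipped rather than binned (far records in a
#' distance distribution, short features in a metagene).  The accounting
#' invariant `sum(counts) + skipped == inputs` holds for every histogram the
#' package produces.
#'
#' @param bin_labels ordered labels.
#' @param counts non-negative counts, same length.
#' @param skipped records tallied outside the bins.
#' @return a `ghistogram` object.
#' @export
ghistogram <- function(bin_labels, counts, skipped = 0L) {
  stopifnot(length(bin_labels) == length(counts), all(counts >= 0))
  structure(list(bin_labels = bin_labels, counts = as.numeric(counts),
                 total = sum(counts), skipped = as.numeric(skipped)),
            class = "ghistogram")
}

#' @export
print.ghistogram <- function(x, ...) {
  cat(sprintf("<ghistogram: %d bins, total %g, skipped %g>\n",
              length(x$bin_labels), x$total, x$skipped))
  invisible(x)
}

tabulate_histogram <- function(values, skipped = 0L) {
  if (length(values) == 0L) return(ghistogram(numeric(0), numeric(0), skipped))
  tab <- table(values)
  ghistogram(as.numeric(names(tab)), as.numeric(tab), skipped)
}

#' Read-size distribution
#'
#' Histogram of spliced read sizes — the plot where a 28-30 nt piRNA
#' population shows up as a sharp peak.
#'
#' @param x a `gintervals` of reads.
#' @return a [ghistogram()] keyed by size (nt).
#' @export
size_distribution <- function(x) tabulate_histogram(iv_size(x))

#' Copy-number distribution
#'
#' Histogram of the `copies` tag (the number of times each distinct
#' sequence was obtained).  Reads without the tag count as single copies.
#'
#' @param x a `gintervals` of reads.
#' @return a [ghistogram()].
#' @export
copies_distribution <- function(x) {
  tabulate_histogram(iv_tag(x, "copies", 1))
}

#' Exons-per-read (or members-per-cluster) distribution
#'
#' @param x a `gintervals`; for clusters the `n_elements` column is used,
#'   otherwise the number of exons per record.
#' @return a [ghistogram()].
#' @export
exons_distribution <- function(x) {
  v <- if ("n_elements" %in% names(x)) x$n_elements
  else vapply(seq_len(nrow(x)), function(i) length(iv_exons(x, i)$starts),
              numeric(1))
  tabulate_histogram(v)
}

#' Nucleotide composition of read sequences
#'
#' Global mode gives one frequency per base over all bases; per-position
#' mode gives, for each 5'-anchored read position, the base frequencies
#' among the reads long enough to reach it (each position normalized to 1).
#' `U` is mapped to `T`; anything outside `ACGTN` is rejected.
#'
#' @param sequences character vector or `Biostrings::DNAStringSet`.
#' @param per_position logical.
#' @return global mode: named numeric vector over `A,C,G,T,N`;
#'   per-position mode: matrix `position x base`.
#' @export
nucleotide_composition <- function(sequences, per_position = FALSE) {
  sequences <- toupper(as.character(sequences))
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  if (any(grepl("[^ACGTN]", sequences)))
    stop("sequence contains a non-IUPAC character (alphabet ACGTNU)")
  bases <- c("A", "C", "G", "T", "N")
  chars <- strsplit(sequences, "", fixed = TRUE)
  if (!per_position) {
    tab <- table(factor(unlist(chars), levels = bases))
    return(setNames(as.numeric(tab) / max(1, sum(tab)), bases))
  }
  maxlen <- max(lengths(chars), 0)
  out <- matrix(0, nrow = maxlen, ncol = length(bases),
                dimnames = list(seq_len(maxlen), bases))
  for (p in seq_len(maxlen)) {
    at <- vapply(chars, function(ch) if (length(ch) >= p) ch[p] else NA_character_,
                 character(1))
    tab <- table(factor(at[!is.na(at)], levels = bases))
    out[p, ] <- as.numeric(tab) / max(1, sum(tab))
  }
  out
}

#' Chromosome density profile
#'
#' Tiles each chromosome into fixed windows of `bin_size` nucleotides and
#' assigns each record to the tile containing its footprint midpoint
#' `floor((start + end - 1) / 2)`, so no record is counted twice across a
#' tile boundary.
#'
#' @param x a `gintervals`.
#' @param bin_size tile width (nt), `> 0`.
#' @return named list of [ghistogram()]s, one per chromosome, labelled by
#'   tile start coordinate.
#' @export
density_profile <- function(x, bin_size) {
  stopifnot(bin_size > 0)
  mid <- floor((x$start + x$end - 1) / 2)
  tile <- mid %/% bin_size
  out <- list()
  for (chr in sort(unique(x$chrom))) {
    t_chr <- tile[x$chrom == chr]
    rng <- 0:max(t_chr)
    counts <- tabulate(t_chr + 1L, nbins = length(rng))
    out[[chr]] <- ghistogram(rng * bin_size, counts)
  }
  out
}

#' Distance-to-nearest-reference distribution
#'
#' For each query, the gap distance ([iv_distance()]) to its nearest
#' reference on the same chromosome.  With `strand_relative = TRUE` the
#' distance is signed, negative when the query lies 5' of the reference on
#' the reference's strand.  Queries farther than `max_distance` or on
#' chromosomes without references are tallied in `skipped`, not binned.
#'
#' @param queries,references `gintervals`.
#' @param strand_relative sign the distances.
#' @param max_distance tally cutoff (nt).
#' @return a [ghistogram()] over distances with per-query distances attached
#'   as attribute `"distances"` (`NA` = skipped).
#' @export
distance_distribution <- function(queries, references,
                                  strand_relative = FALSE,
                                  max_distance = Inf) {
  n <- nrow(queries)
  dists <- rep(NA_real_, n)
  by_chr <- split(seq_len(nrow(references)), references$chrom)
  for (i in seq_len(n)) {
    cand <- by_chr[[queries$chrom[i]]]
    if (is.null(cand)) next
    gaps <- pmax(0, pmax(queries$start[i], references$start[cand]) -
                   pmin(queries$end[i], references$end[cand]))
    j <- cand[which.min(gaps)]
    d <- min(gaps)
    if (d > max_distance) next
    if (strand_relative && d > 0) {
      query_left <- queries$end[i] <= references$start[j]
      ref_minus <- references$strand[j] == "-"
      # upstream = left of a +/unstranded reference, or right of a - one
      if ((query_left && !ref_minus) || (!query_left && ref_minus)) d <- -d
    }
    dists[i] <- d
  }
  h <- tabulate_histogram(dists[!is.na(dists)], skipped = sum(is.na(dists)))
  attr(h, "distances") <- dists
  h
}

coverage_vectors <- function(reads, chrom_ends) {
  # per-chromosome per-nt read depth via difference arrays
  covs <- list()
  for (chr in names(chrom_ends)) {
    len <- chrom_ends[[chr]]
    dv <- numeric(len + 1)
    sel <- which(reads$chrom == chr)
    if (length(sel)) {
      s <- pmin(pmax(reads$start[sel], 0), len) + 1
      e <- pmin(reads$end[sel], len) + 1
      for (k in seq_along(sel)) {
        dv[s[k]] <- dv[s[k]] + 1
        dv[e[k]] <- dv[e[k]] - 1
      }
    }
    covs[[chr]] <- cumsum(dv[-length(dv)])
  }
  covs
}

#' Anchored and meta-gene coverage profiles
#'
#' Computes the average per-nucleotide read depth around feature anchors,
#' oriented 5' to 3' by feature strand, for comparing e.g. nucleosome or
#' histone-modification signal with annotations:
#' \describe{
#'   \item{`tss` / `tes`}{depth at offsets `-flank .. +flank` around the
#'     transcription start (or end) site, averaged over features.}
#'   \item{`metagene`}{each feature's footprint divided into `n_bins` equal
#'     bins; per-bin mean depth, averaged across features.  Features shorter
#'     than `n_bins` are skipped and tallied.}
#' }
#'
#' @param signal_reads a `gintervals` of signal reads (depth counts every
#'   overlapping read at every covered nucleotide).
#' @param features stranded `gintervals` (unstranded treated as `+`).
#' @param anchor `"tss"`, `"tes"` or `"metagene"`.
#' @param flank half-window around the anchor (nt).
#' @param n_bins number of metagene bins.
#' @return an `anchor_profile` list: `offsets`, `mean_signal`,
#'   `n_contributors`, `skipped`.
#' @export
anchor_profile <- function(signal_reads, features,
                           anchor = c("tss", "tes", "metagene"),
                           flank = 1000, n_bins = 100) {
  anchor <- match.arg(anchor)
  stopifnot(nrow(features) > 0L)
  ends <- c(signal_reads$end, features$end + flank)
  chroms <- c(signal_reads$chrom, features$chrom)
  chrom_ends <- tapply(ends, chroms, max)
  covs <- coverage_vectors(signal_reads, as.list(chrom_ends))
  minus <- features$strand == "-"
  if (anchor %in% c("tss", "tes")) {
    offsets <- (-flank):flank
    acc <- numeric(length(offsets))
    ncontrib <- numeric(length(offsets))
    for (i in seq_len(nrow(features))) {
      cov <- covs[[features$chrom[i]]]
      if (is.null(cov)) next
      at_start <- (anchor == "tss") != minus[i]  # tss:+ start; tes:+ end
      pos0 <- if (at_start) features$start[i] else features$end[i] - 1
      # offset o is o nt 3' of the anchor: genomic pos0 + o on '+', pos0 - o on '-'
      pos <- if (minus[i]) pos0 - offsets else pos0 + offsets
      ok <- pos >= 0 & pos < length(cov)
      v <- numeric(length(offsets))
      v[ok] <- cov[pos[ok] + 1]
      acc <- acc + ifelse(ok, v, 0)
      ncontrib <- ncontrib + ok
    }
    mean_signal <- ifelse(ncontrib > 0, acc / pmax(1, ncontrib), NA_real_)
    return(structure(list(offsets = offsets, mean_signal = mean_signal,
                          n_contributors = ncontrib, skipped = 0L),
                     class = "anchor_profile"))
  }
  # metagene
  acc <- numeric(n_bins); ncontrib <- numeric(n_bins); skipped <- 0L
  for (i in seq_len(nrow(features))) {
    len <- features$end[i] - features$start[i]
    cov <- covs[[features$chrom[i]]]
    if (len < n_bins || is.null(cov)) { skipped <- skipped + 1L; next }
    v <- cov[(features$start[i] + 1):features$end[i]]
    edges <- floor(seq(0, len, length.out = n_bins + 1))
    bins <- vapply(seq_len(n_bins), function(b)
      mean(v[(edges[b] + 1):edges[b + 1]]), numeric(1))
    if (minus[i]) bins <- rev(bins)
    acc <- acc + bins
    ncontrib <- ncontrib + 1
  }
  mean_signal <- ifelse(ncontrib > 0, acc / pmax(1, ncontrib), NA_real_)
  structure(list(offsets = seq_len(n_bins), mean_signal = mean_signal,
                 n_contributors = ncontrib, skipped = skipped),
            class = "anchor_profile")
}

#' Render a histogram or profile to PNG + CSV
#'
#' The numeric table behind the plot is always written next to the image
#' (same path with a `.csv` extension): the CSV is the contractual output,
#' the image is a convenience.
#'
#' @param x a [ghistogram()], `anchor_profile`, or the list returned by
#'   [density_profile()].
#' @param path output PNG path.
#' @param main plot title.
#' @return invisibly, the CSV path.
#' @export
render_plot <- function(x, path, main = "") {
  csv <- sub("\\.png$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  if (inherits(x, "ghistogram")) {
    if (length(x$counts) == 0L) stop("empty data: nothing to plot")
    tab <- data.table(bin = x$bin_labels, count = x$counts)
    fwrite(tab, csv)
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    graphics::barplot(x$counts, names.arg = x$bin_labels, main = main,
                      xlab = "bin", ylab = "count", col = "steelblue")
  } else if (inherits(x, "anchor_profile")) {
    if (all(is.na(x$mean_signal))) stop("empty data: nothing to plot")
    tab <- data.table(offset = x$offsets, mean_signal = x$mean_signal,
                      n_contributors = x$n_contributors)
    fwrite(tab, csv)
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    graphics::plot(x$offsets, x$mean_signal, type = "l", main = main,
                   xlab = "offset", ylab = "mean depth", col = "firebrick")
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "ghistogram"))) {
    if (length(x) == 0L) stop("empty data: nothing to plot")
    tab <- rbindlist(lapply(names(x), function(chr)
      data.table(chrom = chr, bin = x[[chr]]$bin_labels,
                 count = x[[chr]]$counts)))
    fwrite(tab, csv)
    grDevices::png(path, width = 900, height = 250 * max(1, length(x)))
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(length(x), 1))
    for (chr in names(x))
      graphics::plot(x[[chr]]$bin_labels, x[[chr]]$counts, type = "h",
                     main = paste(main, chr), xlab = "position",
                     ylab = "records", col = "darkgreen")
  } else stop("unsupported object for render_plot")
  invisible(csv)
}
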