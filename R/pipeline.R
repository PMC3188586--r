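#' piRNA cluster discovery pipeline
#'
#' The worked end-to-end analysis: starting from mapped reads, keep the
#' 28-30 nt size class (excluding other small-RNA species), merge
#' overlapping reads into strand-specific clusters, keep clusters with at
#' least `min_elements` members, and — because clusters supported only by
#' multi-mapping reads may not really live at their locus — keep only the
#' clusters containing at least one uniquely mapping read.  The surviving
#' clusters are written as GFF3 and spreadsheet CSV together with a
#' chromosome density profile (PNG + CSV).
#'
#' One line per stage (records in / records out) is logged to standard
#' error unless `quiet = TRUE`.
#'
#' @param reads a `gintervals` of mapped reads, or a path to a SAM file.
#' @param out_dir output directory; created if needed.
#' @param min_size,max_size inclusive read-size window (nt); default 28-30.
#' @param min_elements minimum cluster member count (default 10).
#' @param require_unique_mapper drop clusters without a unique mapper.
#' @param density_bin_size chromosome density tile width (nt).
#' @param quiet suppress stage logging.
#' @return invisible list: `clusters` (final cluster table), `stage_counts`
#'   (named record counts after every stage), output `files`.
#' @export
pirna_pipeline <- function(reads, out_dir = tempfile("pirna"),
                           min_size = 28, max_size = 30,
                           min_elements = 10, require_unique_mapper = TRUE,
                           density_bin_size = 10000, quiet = FALSE) {
  if (is.character(reads)) reads <- read_sam(reads)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, n_in, n_out) {
    if (!quiet)
      message(sprintf("[pirna-pipeline] %-22s %8d -> %8d", stage, n_in, n_out))
  }
  counts <- c(mapped_reads = nrow(reads))

  sized <- filter_by_size(reads, min_size, max_size)
  log_stage("size-filter", nrow(reads), nrow(sized))
  counts["size_filtered"] <- nrow(sized)

  clusters <- clusterize(sized, max_distance = 0, strand_specific = TRUE)
  log_stage("clusterize", nrow(sized), nrow(clusters))
  counts["clusters"] <- nrow(clusters)

  big <- filter_clusters(clusters, min_elements = min_elements)
  log_stage("cluster-size-filter", nrow(clusters), nrow(big))
  counts["clusters_min_elements"] <- nrow(big)

  final <- big
  if (require_unique_mapper) {
    uniq <- filter_by_tags(sized, exact_hits = 1)
    log_stage("unique-mappers", nrow(sized), nrow(uniq))
    counts["unique_mappers"] <- nrow(uniq)
    final <- filter_clusters(big, min_elements = 1,
                             require_unique_mapper = TRUE)
    log_stage("unique-mapper-rescue", nrow(big), nrow(final))
  }
  counts["final_clusters"] <- nrow(final)

  files <- list(gff3 = file.path(out_dir, "clusters.gff3"),
                csv = file.path(out_dir, "clusters.csv"),
                density_png = file.path(out_dir, "density.png"))
  write_gff3(final, files$gff3)
  write_spreadsheet(final, files$csv)
  if (nrow(final) > 0L) {
    dens <- density_profile(final, density_bin_size)
    files$density_csv <- render_plot(dens, files$density_png,
                                     main = "cluster density")
  }
  invisible(list(clusters = final, stage_counts = counts, files = files))
}
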