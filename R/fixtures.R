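#' Specification of a synthetic mapped-read fixture
#'
#' Describes a genome with planted small-RNA cluster structure, emulating
#' reads obtained from immuno-precipitation of a Piwi protein and mapped to
#' a genome.  The defaults describe the validation scenario used throughout
#' the package: a 2 Mb chromosome carrying 5 genuine piRNA-like clusters
#' (>= 10 reads of 28-30 nt, each containing at least one unique mapper),
#' 3 decoy clusters too small to pass the member threshold, 1 decoy cluster
#' made only of multi-mappers, and scattered background reads with sizes
#' drawn from 20-35 nt outside the piRNA core.
#'
#' @param seed RNG seed; identical seeds give byte-identical output files.
#' @param chromosomes named integer vector of chromosome lengths.
#' @param n_clusters number of planted qualifying clusters.
#' @param cluster_reads inclusive range of member counts for planted
#'   clusters (each also receives at least one unique mapper).
#' @param cluster_span inclusive range of cluster footprint widths (nt).
#' @param n_small_decoys clusters with fewer than `small_decoy_reads[2]+1`
#'   members (below the member threshold).
#' @param small_decoy_reads member-count range for small decoys.
#' @param n_multimapper_decoys clusters (>= 10 members) made exclusively of
#'   multi-mappers.
#' @param read_size_core inclusive size range of cluster reads (the piRNA
#'   core, 28-30 nt).
#' @param fraction_multi_mappers fraction of planted-cluster reads emitted
#'   as multi-mappers (hit count > 1).
#' @param n_background background reads scattered uniformly, sizes 20-35 nt
#'   excluding the core so the size filter removes them.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         chromosomes = c(chr1 = 2000000L),
                         n_clusters = 5L,
                         cluster_reads = c(12L, 40L),
                         cluster_span = c(800L, 2000L),
                         n_small_decoys = 3L,
                         small_decoy_reads = c(3L, 9L),
                         n_multimapper_decoys = 1L,
                         read_size_core = c(28L, 30L),
                         fraction_multi_mappers = 0.2,
                         n_background = 300L) {
  spec <- list(seed = seed, chromosomes = chromosomes,
               n_clusters = n_clusters, cluster_reads = cluster_reads,
               cluster_span = cluster_span, n_small_decoys = n_small_decoys,
               small_decoy_reads = small_decoy_reads,
               n_multimapper_decoys = n_multimapper_decoys,
               read_size_core = read_size_core,
               fraction_multi_mappers = fraction_multi_mappers,
               n_background = n_background)
  if (max(spec$cluster_span) * 2 > min(chromosomes))
    stop("inconsistent spec: cluster span too large for the chromosomes")
  structure(spec, class = "fixture_spec")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic mapped-read fixture
#'
#' Writes three files into `dir`: `reads.sam` (mapped reads with `NH` hit
#' counts and `NM` mismatch tags; a multi-mapper is emitted once per
#' placement with `NH > 1`), `annotation.gff3` (the planted cluster spans),
#' and `truth.csv` (cluster coordinates, member counts, and whether each
#' cluster should survive the piRNA pipeline).  Cluster sites are laid out
#' on a deterministic grid with at least 10 kb between sites so planted
#' clusters can never merge with one another or with background.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisible list with file paths, the truth `data.table` and the
#'   generated reads.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  chrom <- names(spec$chromosomes)[1]
  clen <- spec$chromosomes[[1]]
  n_sites <- spec$n_clusters + spec$n_small_decoys + spec$n_multimapper_decoys
  # well-separated anchor grid: sites every max span + 10 kb
  pitch <- max(spec$cluster_span) + 10000
  stopifnot(n_sites * pitch < clen)
  anchors <- 20000 + (seq_len(n_sites) - 1L) * pitch
  anchors <- anchors + rint(n_sites, c(0, 2000))
  kind <- c(rep("planted", spec$n_clusters),
            rep("small_decoy", spec$n_small_decoys),
            rep("multimapper_decoy", spec$n_multimapper_decoys))
  truth <- data.table(cluster = sprintf("truth_%02d", seq_len(n_sites)),
                      kind = kind, chrom = chrom,
                      start = NA_real_, end = NA_real_,
                      n_reads = NA_integer_, strand = NA_character_,
                      qualifies = kind == "planted")
  reads <- list()
  add_read <- function(name, start, size, strand, nh, nm = 0L) {
    reads[[length(reads) + 1L]] <<- list(
      chrom = chrom, start = start, end = start + size, strand = strand,
      name = name, tags = list(nbOccurrences = nh, nbMismatches = nm))
  }
  rid <- 0L
  for (s in seq_len(n_sites)) {
    span <- rint(1, spec$cluster_span)
    n_reads <- switch(kind[s],
                      planted = rint(1, spec$cluster_reads),
                      small_decoy = rint(1, spec$small_decoy_reads),
                      multimapper_decoy = rint(1, spec$cluster_reads))
    strand <- sample(c("+", "-"), 1)
    sizes <- rint(n_reads, spec$read_size_core)
    # dense tiling so members always chain into one cluster
    step <- max(1, floor((span - max(sizes)) / n_reads))
    starts <- anchors[s] + (seq_len(n_reads) - 1L) * min(step, 20)
    nh <- rep(1L, n_reads)
    if (kind[s] == "multimapper_decoy") {
      nh <- rint(n_reads, c(2L, 8L))
    } else if (kind[s] == "planted") {
      multi <- runif(n_reads) < spec$fraction_multi_mappers
      multi[1] <- FALSE  # guarantee the unique-mapper rescue witness
      nh[multi] <- rint(sum(multi), c(2L, 8L))
    }
    for (k in seq_len(n_reads)) {
      rid <- rid + 1L
      add_read(sprintf("read_%05d", rid), starts[k], sizes[k], strand,
               nh[k], rbinom(1, 1, 0.2))
    }
    set(truth, s, c("start", "end", "n_reads", "strand"),
        list(min(starts), max(starts + sizes), n_reads, strand))
  }
  # background: sizes outside the piRNA core, scattered genome-wide
  bg_sizes <- sample(setdiff(20:35, seq(spec$read_size_core[1],
                                        spec$read_size_core[2])),
                     spec$n_background, replace = TRUE)
  bg_starts <- sample.int(clen - 40L, spec$n_background)
  for (k in seq_len(spec$n_background)) {
    rid <- rid + 1L
    add_read(sprintf("read_%05d", rid), bg_starts[k], bg_sizes[k],
             sample(c("+", "-"), 1), sample(c(1L, 1L, 2L), 1),
             rbinom(1, 1, 0.2))
  }
  # a multi-mapper is one sequencing read seen at several loci: emit its
  # secondary placements, isolated in the site-free part of the chromosome
  far_zone <- c(max(anchors) + 50000, clen - 100)
  for (r in reads) {
    nh <- r$tags$nbOccurrences
    if (nh <= 1L) next
    alt <- sample(seq(far_zone[1], far_zone[2]), nh - 1L)
    for (p in alt) {
      rid <- rid + 1L
      add_read(r$name, p, r$end - r$start, r$strand, nh, r$tags$nbMismatches)
    }
  }
  x <- gintervals(
    chrom = vapply(reads, `[[`, character(1), "chrom"),
    start = vapply(reads, `[[`, numeric(1), "start"),
    end = vapply(reads, `[[`, numeric(1), "end"),
    strand = vapply(reads, `[[`, character(1), "strand"),
    name = vapply(reads, `[[`, character(1), "name"),
    tags = lapply(reads, `[[`, "tags"))
  sam <- file.path(dir, "reads.sam")
  gff <- file.path(dir, "annotation.gff3")
  csv <- file.path(dir, "truth.csv")
  write_sam(x, sam, chrom_sizes = spec$chromosomes)
  ann <- gintervals(truth$chrom, truth$start, truth$end, truth$strand,
                    truth$cluster,
                    tags = lapply(truth$kind, function(k) list(kind = k)))
  write_gff3(ann, gff)
  fwrite(truth, csv)
  invisible(list(dir = dir, sam = sam, gff3 = gff, truth_csv = csv,
                 truth = truth, reads = x))
}

#' Simulate two-condition read sets over a gene panel
#'
#' A simple generator for differential expression experiments: regions of
#' given lengths are laid out on one chromosome with 1 kb spacers; reads of
#' 30 nt are placed uniformly within each region, with per-region expected
#' counts `depth * fold_change` in condition B versus `depth` in condition
#' A (Poisson-distributed).
#'
#' @param region_lengths numeric vector of region footprint lengths (nt).
#' @param depth expected read count per region in condition A (scalar or
#'   per-region vector, e.g. proportional to length for a uniform per-nt
#'   rate).
#' @param fold_change per-region fold change for condition B (recycled).
#' @param read_size read length (nt).
#' @param seed RNG seed.
#' @return list with `regions`, `reads_a`, `reads_b` (`gintervals`).
#' @export
simulate_two_conditions <- function(region_lengths, depth = 50,
                                    fold_change = 1, read_size = 30,
                                    seed = 1L) {
  set.seed(seed)
  n <- length(region_lengths)
  fold_change <- rep_len(fold_change, n)
  depth <- rep_len(depth, n)
  starts <- cumsum(c(10000, head(region_lengths, -1) + 1000))
  regions <- gintervals("chrSim", starts, starts + region_lengths,
                        strand = "+", name = sprintf("gene_%03d", seq_len(n)))
  sample_reads <- function(rates, cond) {
    counts <- rpois(n, rates)
    rs <- unlist(lapply(seq_len(n), function(i) {
      if (counts[i] == 0L) return(numeric(0))
      starts[i] + sample.int(max(1, region_lengths[i] - read_size),
                             counts[i], replace = TRUE) - 1
    }))
    if (length(rs) == 0L) return(gintervals_empty())
    gintervals("chrSim", rs, rs + read_size, strand = "+",
               name = sprintf("%s_read_%06d", cond, seq_along(rs)))
  }
  list(regions = regions,
       reads_a = sample_reads(depth, "A"),
       reads_b = sample_reads(depth * fold_change, "B"))
}
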