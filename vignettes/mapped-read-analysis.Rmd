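---
title: "Analysing mapped RNA-seq reads with rnatoolbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing mapped RNA-seq reads with rnatoolbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatoolbox)
library(data.table)
```

## Scope

Once short reads have been mapped to a genome, most of the biology still
has to be extracted from the resulting coordinate sets: which reads fall in
annotated features, where reads pile up into clusters, which regions differ
between two conditions, what the size and positional distributions look
like.  `rnatoolbox` provides those downstream operations as composable R
functions plus a thin shell interface, with an indexed interval engine
underneath so that large coordinate sets stay queryable.

This vignette documents the model and the numerical choices; it is the
package's reference for *why* things are computed the way they are.

## The interval model

Every record — a mapped read, an annotation, a cluster — is a row of a
`gintervals` table: chromosome, footprint `[start, end)`, strand
(`+`/`-`/`*`), an optional list of exon sub-intervals and a tag map.
Three conventions are fixed once, at the model level:

* **Coordinates are 0-based, half-open, everywhere.**  GFF3 and SAM are
  1-based inclusive and BED is 0-based half-open; conversion happens only
  inside the format readers/writers, never in analysis code.  A single
  internal convention removes the usual class of off-by-one defects in
  overlap and adjacency logic: two intervals overlap iff
  `a.start < b.end && b.start < a.end`, book-ended intervals
  (`a.end == b.start`) share no base.
* **Size means spliced size.**  The size of a record is the sum of its exon
  lengths, not `end - start`.  A 29-nt read whose alignment spans an intron
  is still a 29-nt read, which is what a small-RNA size filter must see.
* **Unstranded records (`*`) match both strands** in strand-specific
  comparisons, so strand-unannotated references are not silently dropped.

The spliced-overlap question (does a read overlap a feature if only its
intron does?) has no universally right answer, so `iv_overlaps()` exposes
an `exon_aware` flag: off, footprints are compared; on, at least one exon
pair must share a base.  Footprint comparison is the default used by the
higher-level operations.

## The indexed interval store

`interval_store()` answers "which stored intervals overlap `[s, e)` on this
chromosome" without scanning the table.  Each interval is filed under the
smallest bin that fully contains it in a five-level nested-bin hierarchy
(128 kb leaf bins, then 1 Mb, 8 Mb, 64 Mb, 512 Mb; level offsets 585, 73,
9, 1, 0 — the standard genome-browser scheme).  A query enumerates, at each
level, the bins its range touches; that set simultaneously covers the
query's ancestors and all contained descendants, so the probe count is
proportional to hierarchy depth plus the number of leaf bins the range
spans — never to the number of stored records.  Records are kept in a table
keyed on `(chromosome, bin)`, so each probe is a sublinear point lookup,
and candidate hits are then verified against actual coordinates.

Two deliberate edge policies:

* Intervals reaching beyond 512 Mb (unusual scaffolds) fall into the root
  bin — correct, merely slower — rather than erroring at ingestion.
* Insertion has multiset semantics: duplicate records are retained.

A store given a path persists itself as a single plain-text table on
`store_close()` and reopens from it; exons and tags survive the round trip
(tags serialized as JSON).  `store_query(..., count_probes = TRUE)` exposes
the probed-bin count, which the test suite uses to assert sublinear access
on a 100,000-record store.

## Formats

* **SAM** (plain text): unmapped records are skipped, FLAG bit 0x10 sets
  the minus strand, and the CIGAR string is walked to recover exons — `M`,
  `=`, `X`, `D` consume reference within the current exon, `N` closes an
  exon (an intron), `I`/`S`/`H`/`P` consume none.  `NH` is exposed as the
  `nbOccurrences` hit count, `NM` as `nbMismatches`; unknown tags pass
  through verbatim.
* **BED** 3/6/12: coordinates pass through unchanged; BED12 blocks expand
  to exons; `.` means unstranded.
* **GFF3**: read via a standard parser, with child features sharing a
  `Parent` assembled into one multi-exon record named by the parent ID; an
  orphaned child is kept standalone with a warning.  The writer emits one
  `match` parent plus `match_part` children for multi-exon records, the
  standard representation for mapped reads.
* **Generic tabular mapper output**: one column-mapped reader
  (`tabular_spec()`) replaces the long tail of per-aligner dialects; the
  shipped `blast8` preset shows the pattern (1-based inclusive subject
  coordinates, a reversed pair encoding the minus strand).
* **Spreadsheet export** is CSV — opens in Excel, stays diffable.

Round-trip identity (coordinates, strand, exon structure, recognized tags)
for GFF3, BED12 and SAM is asserted on randomized multi-exon records.

Readers load whole files; the package targets desk-scale inputs (millions
of records), for which `data.table`-backed parsing is both faster and
simpler than incremental streaming.

## Filtering and clustering

`filter_by_size()` keeps reads whose *spliced* size lies in an inclusive
window — 28–30 nt being the canonical piRNA setting.  `filter_by_tags()`
applies hit-count and mismatch constraints; a read missing a tag that a
constraint needs is dropped and counted in an explicit tally, so nothing
disappears silently.

`select_by_overlap()` keeps (or excludes) reads overlapping a reference
set, with strand-relative flanks applied to the references first — an
upstream flank of 500 nt turns a gene set into a promoter screen.  The
minimum overlap defaults to 1 nt, the most permissive reading.  Keep and
exclude modes partition the input exactly; kept reads learn which
references they hit via an `overlapping_refs` tag.

`clusterize()` merges reads into clusters by single linkage per chromosome
and, by default, per strand (small-RNA clusters are strand-coherent loci;
`strand_specific = FALSE` disables the split).  With `max_distance = 0` a
read must share at least one nucleotide with the open cluster — book-ended
reads stay apart, consistent with half-open semantics — while a positive
`max_distance` also bridges gaps up to that length.  Clusters carry their
member count, member names and a `has_unique_mapper` flag (at least one
member with hit count 1).  The member-count total always equals the input
read count, and re-clustering cluster footprints with the same parameters
is a fixed point; both are asserted as invariants.

`merge_bidirectional()` looks for two-strand patterns after per-strand
clustering: a `+` and a `-` cluster overlapping (double-strand
transcription) or a `-` cluster ending within a user window upstream of a
`+` cluster's start (the head-to-head geometry of a putative bidirectional
promoter).  The gap is measured between nearest footprint ends, the same
definition `iv_distance()` uses.

## Differential expression

For each reference region, reads of both conditions are counted
(`count_reads_per_region()`: a read increments every region it overlaps by
at least 1 nt; library totals stay the read totals).  The region count and
the library remainder form a 2×2 table per region, tested with
`fisher_exact()` — the exact conditional hypergeometric test, two-sided by
probability mass: the p-value sums the probabilities of all tables (margins
fixed) at most as probable as the observed one, with a `1e-7` relative
guard against floating-point ties.  One-sided alternatives are available
via a flag.  `fdr_filter()` applies Benjamini–Hochberg step-up adjustment
(`stats::p.adjust`) and marks `q <= alpha`.

Three normalizations:

1. **Mean scaling** (default): both libraries scaled to the average of the
   two totals.  Simple, and adequate when expression changes are not
   concentrated in the most-expressed regions.
2. **Interquartile scaling**: assumes moderately expressed regions are not
   differential.  Regions are ranked by their cross-condition average
   count; condition B is rescaled so the interquartile set (0-based ranks
   `floor(n/4) <= i < floor(3n/4)`) carries equal total count in both
   conditions.  The defining property — equal IQR sums after scaling — is
   asserted to 1e-9 relative error on randomized tables.
3. **Window averaging**: count-based tests grow more powerful with region
   length, so at equal per-nucleotide signal, long regions reach
   significance first.  This scheme sets a window to the spliced size of
   the smallest region, slides it in 1-nt steps along each region's
   footprint (`L - w + 1` placements; one placement when `L <= w`), and
   replaces the raw count by the mean over placements.  The mean is
   computed in closed form from each read's number of overlapping
   placements, so the cost is linear in read count, not `L × reads`.
   In `diff_expr(normalization = "window")` the window-averaged counts are
   additionally mean-scaled for library depth: window averaging replaces
   *what* is counted, but the exact test still needs comparable margins,
   and without depth equalization a library-size difference would read as
   signal in every region.  (The interquartile scheme is deliberately not
   composed with window counting; the two encode different assumptions.)

Fractional normalized counts are rounded half-to-even before testing,
since the hypergeometric needs integers.

Two statistical behaviors worth knowing:

* **The exact test is conservative at low counts.**  Attainable
  significance levels are discrete, so the null rejection fraction at 0.05
  sits below 0.05 — around 0.045 at ~50 reads/region, approaching 0.0485
  at ~500 reads/region in the package's own calibration study (500
  regions × 200 replicates).  This is a property of exact conditional
  tests, not a defect; the acceptance suite runs the calibration at depth
  500, where the count lattice is fine enough for the question to be
  meaningful.
* **The length bias is real and the window scheme reduces it.**  In the
  packaged simulation (genes of 200 vs 2,000 nt, identical per-nt rate and
  an identical true 2-fold shift against a fixed background library), raw
  counting gives long genes a median −log₁₀ p more than ten times that of
  short genes; window averaging brings the ratio below 2.

## Distributions and profiles

All histogram operations return a `ghistogram` with an explicit `skipped`
tally so the accounting invariant *binned + skipped = inputs* is checkable
everywhere.  Specifics:

* **Chromosome density** assigns each record to the fixed tile containing
  its footprint midpoint `floor((start + end - 1) / 2)` — one tile per
  record, no double counting at tile boundaries.
* **Distance to nearest reference** uses the gap distance; with
  `strand_relative = TRUE` it is signed, negative when the query lies 5′ of
  the reference on the reference's strand.  (Unsigned histograms are a
  trivial fold of the signed data, so the signed form is kept.)  Queries
  beyond `max_distance` or on reference-free chromosomes are tallied, not
  binned.
* **Anchor profiles** average per-nucleotide read depth (every overlapping
  read counts at every covered base, not just its midpoint) around TSS or
  TES anchors oriented 5′→3′ by feature strand, or across `n_bins`
  equal-width bins of each feature body (meta-gene mode; default 100 bins,
  TSS flank default 1,000 nt).  Features shorter than the bin count are
  skipped and tallied.  Strand symmetry — a minus-strand feature yields the
  reverse of the plus-strand profile — is asserted in the tests.
* **Nucleotide composition** works globally or per 5′-anchored position,
  each position normalized over the reads long enough to reach it; `U`
  maps to `T`, anything outside `ACGTN` is an error.

`render_plot()` writes a PNG **and** the numeric table behind it as CSV;
the CSV is the contractual output, the image a convenience.

## The piRNA cluster pipeline

`pirna_pipeline()` chains the pieces into the worked small-RNA analysis:

1. keep reads of spliced size 28–30 nt (excludes other small-RNA classes);
2. cluster strand-specifically with `max_distance = 0`;
3. keep clusters with ≥ 10 members;
4. keep clusters containing at least one uniquely mapping member — a locus
   supported only by multi-mappers may not really live where it was placed.
   Rescue is by *membership* (a member with hit count 1), not by
   re-overlap of an external read set, which matches the intent of keeping
   clusters that contain such a read;
5. write GFF3 + spreadsheet CSV + a chromosome density plot.

Each stage logs records-in/records-out to standard error, and the logged
counts are non-increasing through the filter stages.  The pipeline output
is invariant to input record order.

## The synthetic fixture

`generate_fixture()` emulates a Piwi immuno-precipitation read set mapped
to a genome, with known ground truth.  The default scenario — the study
condition used by the acceptance suite — is one 2-Mb chromosome carrying:

* 5 genuine clusters: 12–40 reads of 28–30 nt, densely tiled over
  800–2,000-nt spans, each guaranteed one uniquely mapping member, ~20%
  multi-mappers;
* 3 small decoys (3–9 reads — below the member threshold);
* 1 decoy of comparable size made *only* of multi-mappers;
* 300 background reads with sizes 20–35 nt excluding the 28–30 core,
  scattered uniformly.

Cluster sites sit on a grid with ≥ 10 kb separation so planted loci can
never merge, and each multi-mapper's secondary placements (one SAM record
per placement, `NH` > 1) are isolated in the site-free part of the
chromosome where they cannot assemble into a qualifying cluster.  Identical
seeds give byte-identical output files.

What the fixture does *not* emulate: sequencing error, mismatch-dependent
mapping ambiguity, chromatin-driven background structure, or replicate
variability.  Passing the recovery test therefore shows the pipeline logic
is correct under clean planted structure, not that the thresholds are
optimal for any real library.

Problem sizes used by the validation suite (chosen as comfortable
desk-scale studies): 20 randomized instances of 5,000 intervals × 500
queries for the overlap engine; 100,000 null Fisher tests at depth 500 for
calibration; 80 genes for the length-bias study; 100 replicates for the
4-fold power study; 1,000 records for format round-trips.

## Known limitations

* No replicate-aware dispersion modelling: the Fisher test compares two
  libraries, so biological variability beyond counting noise is outside
  its model (negative-binomial methods exist for that and are out of
  scope here).
* Cluster footprints are spans: member exon structure is not preserved
  through merging.
* BAM/CRAM are not decoded; convert to plain SAM upstream.
* The on-disk store assumes a single writer.
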