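---
title: "Estimating whole-genome coverage from alignment indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whole-genome coverage from alignment indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

A coordinate-sorted BAM file ships with a binary index (`.bai`) whose
*linear index* stores, for every consecutive 16 384-bp window ("tile") of
each reference, the virtual file offset of the first alignment overlapping
it.  A virtual offset packs the byte position of a BGZF block in the
compressed file (upper 48 bits) and an offset within that block's
uncompressed data (lower 16 bits).  Differencing consecutive offsets
therefore tells us *how many compressed bytes of alignment records fall in
each tile* -- without decoding a single record.  Because bytes per record
are roughly constant within a sample, per-tile byte counts are an
effective proxy for read depth: a tile consuming half the genome-wide
median bytes most likely has half the coverage, e.g. a hemizygous
deletion.

`idxcov` turns this observation into a cohort QC pipeline:

1. **index → tile bytes** (`read_bai()` / `read_crai()`,
   `tile_byte_sizes()` / `crai_tile_sizes()`);
2. **tile bytes → scaled coverage**: divide by the genome-wide median of
   nonzero autosomal tile sizes (`compute_baseline()`, `scale_profile()`),
   so 1.0 is the diploid baseline;
3. **cohort QC**: sex-chromosome copy number and sex calls
   (`estimate_copy_number()`, `infer_sex()`), tile-proportion anomaly
   statistics (`tile_proportions()`), reverse-CDF summaries
   (`coverage_cdf()`), and PCA over the byte-quantized cohort matrix
   (`pca_project()`);
4. **outputs**: a BGZF BED coverage matrix, an extended PED QC table, and
   a static+interactive HTML report (`run_indexcov()`).

```{r}
library(idxcov)
res <- run_indexcov(c("a.bam", "b.bam", "c.bam"), "qc-out/")
res$qc
```

## Resolution: what the index can and cannot see

The byte proxy has two noise sources beyond counting noise:

* **Block granularity.**  The within-block part of a virtual offset is an
  *uncompressed* offset, so it cannot be converted exactly to compressed
  bytes.  We map an offset to the scalar position
  `coffset + uoffset / 65536`, which is monotone and sub-block accurate to
  about one compressed BGZF block.  The relative error of a tile's size
  estimate is therefore on the order of `65536 / S`, where `S` is the
  tile's *uncompressed* byte mass (a BGZF block holds 65 536 uncompressed
  bytes).  At 30x short-read coverage `S` is several hundred kilobytes and
  the error is a few percent; at very low depth, or for long-read data
  with few alignments per tile, the estimate degrades -- which is why the
  method is a QC screen, not a CNV caller.
* **Byte-per-record variation.**  Tiles rich in split reads or tags use
  more bytes per alignment and can look "deeper" than they are.

The synthetic-BAM generator (`make_synthetic_bam()`) exposes both knobs:
read length and depth set the per-tile record count, and `pad_bytes`
attaches an `XP:Z` padding tag emulating heavily tagged alignments.  Test
fixtures that assert tight oracle agreement use padded records so that
block granularity stays a small fraction of `S`, per the formula above;
fixtures probing averages (copy number, deletion means) use plain records,
since medians and means over hundreds of tiles are insensitive to
per-tile jitter.

## Design choices

* **Scalar file position.**  `coffset + uoffset / 65536` preserves
  ordering and never loses precision (offsets are held as doubles;
  48-bit compressed offsets are exact well past any real file size).
* **Fill-forward.**  Linear-index entries for tiles the indexer skipped
  are zero; after the first nonzero entry such zeros are replaced by the
  previous offset, so empty tiles get size 0 instead of corrupting the
  difference chain.  The last indexed tile has no successor offset and is
  assigned size 0: a one-tile edge loss that is negligible at 16-kb
  resolution.
* **Genome-wide autosomal baseline.**  The median is taken once over all
  nonzero tiles of non-excluded, non-sex references.  Per-chromosome
  scaling would force every chromosome to 1 and erase exactly the dosage
  signal (X, Y, aneuploidies) the sex plot needs; zero tiles are excluded
  because N-masked gaps would bias the median; sex chromosomes are
  excluded because their dosage varies between sexes while the baseline
  must be diploid.
* **Default exclusion pattern.**  Decoy/alt/unplaced contigs
  (`_random`, `_alt`, `chrUn`, `GL*`, `NC_*`, `hs37d5`, `HLA-*`,
  `hap*`, `chrEBV`) are flagged and kept out of baseline, statistics and
  report; the regex is user-overridable.
* **CRAI re-binning.**  CRAM index slices have sample-specific genomic
  spans, so each slice's bytes are distributed over the fixed 16 384-bp
  grid proportionally to overlap, conserving total bytes exactly.  Each
  index line is treated as an independent byte mass; multi-slice container
  subtleties are below the resolution this method targets.
* **Quantization.**  The cohort PCA matrix stores one byte per value:
  `round(64 * scaled)` clamped to [0, 255], i.e. resolution 1/64 and
  saturation at ~3.98 (copy number 8).  The constant covers every copy
  state the QC plots display while keeping memory at one byte per tile
  per sample.
* **Copy number and sex thresholds.**  CN is twice the *median* scaled
  coverage of a chromosome's usable tiles (robust to segmental CNVs).
  Sex is called from CN X with cut points 0.4 and 1.5: midpoints between
  the integer CN clusters real cohorts form, with a dead zone near zero
  so broken samples (e.g. truncated indexes) are called "unknown" rather
  than male.
* **Usable-tile masks.**  Tiles zero in *every* cohort sample are
  reference gaps and are excluded from tile statistics, PCA and CN
  estimation.  With a single sample, a run of three or more consecutive
  zero tiles is treated as a gap while isolated zeros count as missing
  coverage.
* **Tile statistics.**  Proportions of usable autosomal tiles with scaled
  coverage < 0.15 (`bins.lo`) and outside the closed interval
  [0.85, 1.15] (`bins.out`).  The boundary convention is inclusive:
  exactly 0.85 or 1.15 counts as "in".
* **PCA.**  Computed on the dequantized one-byte matrix over all
  non-excluded references (the whole genome, sex chromosomes included),
  columns centered but not scaled -- every column is already in common
  scaled-coverage units.  The top five components come from an SVD with
  signs fixed so each component's largest-magnitude loading is positive,
  making projections deterministic.
* **Truncated indexes are a result, not an error.**  A `.bai` that ends
  mid-structure yields a flagged all-zero profile: the sample appears in
  every output with CN 0/0, sex code 0 and `bins.lo = 1`, surfacing near
  the origin of the sex plot where an analyst will see it.
* **Report format.**  All plots are generated as inline SVG: text-only,
  byte-deterministic under the `deterministic_html` flag, no graphics
  device required, and hover identification comes free via SVG `<title>`
  elements.  Thumbnails are small SVGs linking to per-chromosome pages.
* **PED layout.**  The standard six pedigree columns (family and sample
  id, unknown parents/phenotype as -9, sex codes 1/2/0) are extended with
  ten named columns: CN per sex chromosome, `bins.in`/`bins.out`/
  `bins.lo`, and PC1..PC5.

## What the synthetic data does and does not emulate

`make_synthetic_bam()` places fixed-length reads by a seeded Poisson
process whose rate is `depth x multiplier`, writes a coordinate-sorted
SAM and hands conversion and indexing to htslib, so the `.bai` under test
is produced by the standard indexer.  Segment multipliers emulate CNVs,
sex-chromosome dosage, assembly gaps (multiplier 0) and GC-like bias
blocks; `pad_bytes` emulates tag-heavy alignments.  The `depth_oracle()`
companion computes exact per-base depth from the alignment records and is
the independent ground truth for every oracle-agreement test.

Not emulated: GC-correlated coverage waves along real genomes, mapping
artifacts in low-complexity regions, split/discordant reads with genuine
SAM tags, duplicate reads, and reference N-runs longer than whole tiles.
Passing tests therefore demonstrate the estimator's arithmetic and its
statistical behaviour under clean Poisson sampling, not robustness to
every real-data artifact -- on real data the original correlation with
per-base depth is expected to be lower, as mapping noise adds variance
the index cannot see.

## Study conditions used by the checks

The shipped checks run at desk scale, chosen once as realistic for the
signal each check probes:

* oracle agreement: a 50-Mb two-reference genome at 10x equivalent depth
  (1-kb reads, 2-kb padding tags), with a 10-Mb half-depth segment and
  2-Mb multiplier blocks between 0.6 and 2.0 emulating coverage
  structure;
* deletion recovery: the same genome uniform except one contiguous 10-Mb
  segment at multiplier 0.5;
* sex/aneuploidy: a six-sample cohort (two XX, three XY, one XYY) with a
  6-Mb autosome, 5-Mb X and 3-Mb Y at 10x;
* batch detection: a 20 x 500 quantized matrix with batch-shared tile
  biases, one batch carrying three-fold tile-level variance;
* uniform-sample tile statistics: a 5-Mb genome at 10x with padded
  records.

## Limitations

* Long-read or very-low-depth data leave too few alignments per tile for
  the byte proxy to be stable.
* The method measures *bytes*, so library artifacts that change bytes per
  read (tag bloat, duplicate spikes) masquerade as coverage changes.
* It is a screen for large anomalies -- megabase-scale CNVs, aneuploidy,
  dead samples, batch effects -- not a base-resolution CNV caller.
* CSI indexes and remote inputs are out of scope; CRAM mode reads only
  the `.crai` plus a `.fai` and never opens the CRAM itself.
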