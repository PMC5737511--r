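#' Describe a synthetic genome and its coverage structure
#'
#' The generator emulates the coverage signal of a short-read WGS sample:
#' reads of fixed length are placed by a Poisson process whose local rate is
#' the global base depth times a per-segment multiplier (1 outside any
#' segment).  Segment multipliers express CNVs (0.5 for a hemizygous
#' deletion, 0 for missing data), sex-chromosome dosage, or GC-like bias.
#'
#' @param refs Data.frame with columns `name` and `length`.
#' @param segments Optional data.frame with columns `ref`, `start`, `end`
#'   (0-based half-open) and `mult` (depth multiplier >= 0) overriding the
#'   baseline multiplier of 1.
#' @param depth Target mean per-base depth at multiplier 1.
#' @param read_length Read length in bases.
#' @param pad_bytes Bytes of an `XP:Z` padding tag appended to every
#'   record, inflating per-record byte size the way heavily tagged (e.g.
#'   split-read) alignments do.
#' @param seed RNG seed; a fixed seed gives byte-identical BAM output.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(refs, segments = NULL, depth = 10,
                        read_length = 100L, pad_bytes = 0L, seed = 1L) {
  stopifnot(is.data.frame(refs), all(c("name", "length") %in% names(refs)),
            all(refs$length >= 1), depth >= 0, read_length >= 1)
  if (!is.null(segments)) {
    stopifnot(all(c("ref", "start", "end", "mult") %in% names(segments)),
              all(segments$mult >= 0),
              all(segments$ref %in% refs$name))
    for (i in seq_len(nrow(segments))) {
      len <- refs$length[match(segments$ref[i], refs$name)]
      if (segments$start[i] < 0 || segments$end[i] > len ||
          segments$start[i] >= segments$end[i]) {
        stop("segment ", i, " outside reference bounds")
      }
    }
  }
  structure(list(refs = refs, segments = segments, depth = depth,
                 read_length = as.integer(read_length),
                 pad_bytes = as.integer(pad_bytes), seed = as.integer(seed)),
            class = "genome_spec")
}

# Piecewise-constant multiplier intervals (0-based half-open) for one
# reference: baseline 1, segments override.
.mult_intervals <- function(spec, ref_name) {
  len <- spec$refs$length[match(ref_name, spec$refs$name)]
  segs <- spec$segments
  if (!is.null(segs)) segs <- segs[segs$ref == ref_name, , drop = FALSE]
  if (is.null(segs) || nrow(segs) == 0L) {
    return(data.frame(start = 0, end = len, mult = 1))
  }
  bp <- sort(unique(c(0, len, segs$start, segs$end)))
  out <- data.frame(start = bp[-length(bp)], end = bp[-1], mult = 1)
  for (i in seq_len(nrow(segs))) {
    hit <- out$start >= segs$start[i] & out$end <= segs$end[i]
    out$mult[hit] <- segs$mult[i]
  }
  out
}

#' Generate a coordinate-sorted, indexed synthetic BAM
#'
#' Read starts are drawn per constant-multiplier interval: the count is
#' Poisson with mean `depth * mult * width / read_length` and positions are
#' uniform, so expected per-base depth equals `depth * mult` away from
#' boundaries.  Records are minimal (fixed CIGAR `<L>M`, mapq 60, no
#' quality string) unless `pad_bytes` adds a padding tag.  The SAM text is
#' converted, sorted and indexed with htslib (via Rsamtools), so the .bai
#' under test is produced by the standard indexer, not by this package.
#'
#' @param spec A [genome_spec()].
#' @param path Output BAM path (`.bam`); the index lands at `<path>.bai`.
#' @param sample_id Value of the read-group `SM` tag; defaults to the file
#'   basename.
#' @return Invisibly, a list with `bam`, `bai` and `n_records`.
#' @export
make_synthetic_bam <- function(spec, path,
                               sample_id = sub("\\.bam$", "", basename(path))) {
  stopifnot(inherits(spec, "genome_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  L <- spec$read_length
  seq_str <- strrep("A", L)
  pad <- if (spec$pad_bytes > 0L) {
    paste0("XP:Z:", strrep("P", spec$pad_bytes))
  } else NULL

  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", spec$refs$name,
                   as.integer(spec$refs$length)),
           sprintf("@RG\tID:rg1\tSM:%s", sample_id))
  writeLines(hdr, sam)

  total <- 0L
  for (r in seq_len(nrow(spec$refs))) {
    iv <- .mult_intervals(spec, spec$refs$name[r])
    starts <- numeric(0)
    for (i in seq_len(nrow(iv))) {
      lo <- iv$start[i]
      hi <- min(iv$end[i], spec$refs$length[r] - L + 1)
      w <- hi - lo
      if (w <= 0 || iv$mult[i] <= 0) next
      n <- stats::rpois(1L, spec$depth * iv$mult[i] * w / L)
      if (n > 0L) starts <- c(starts, lo + floor(stats::runif(n) * w))
    }
    if (length(starts) == 0L) next
    starts <- sort(starts)
    dt <- data.table::data.table(
      qname = sprintf("r%d_%d", r, seq_along(starts)),
      flag = 0L,
      rname = spec$refs$name[r],
      pos = as.integer(starts) + 1L,   # SAM is 1-based
      mapq = 60L,
      cigar = sprintf("%dM", L),
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = seq_str, qual = "*"
    )
    if (!is.null(pad)) dt$tag <- pad
    data.table::fwrite(dt, sam, sep = "\t", col.names = FALSE,
                       quote = FALSE, append = TRUE)
    total <- total + nrow(dt)
  }

  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  bai <- Rsamtools::indexBam(bam)
  invisible(list(bam = bam, bai = unname(bai), n_records = total))
}

#' Exact per-tile depth from alignment records (test oracle)
#'
#' The independent ground truth the index-based estimate is compared
#' against: per-base depth is accumulated from the actual alignment
#' records, averaged within each 16384-bp tile, and (optionally) divided by
#' the genome-wide median of nonzero tile means -- the same scaling applied
#' to the index-derived profiles.
#'
#' @param bam_path BAM file to read.
#' @param refs Reference table ([read_bam_references()]).
#' @param scaled Divide by the genome-wide median of nonzero tiles?
#' @return Named list of per-tile mean depths, one vector per reference.
#' @export
depth_oracle <- function(bam_path, refs, scaled = TRUE) {
  param <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth"))
  rec <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
  out <- vector("list", nrow(refs))
  names(out) <- refs$name
  for (r in seq_len(nrow(refs))) {
    len <- refs$length[r]
    n_tiles <- ceiling(len / TILE_WIDTH)
    sel <- !is.na(rec$rname) & rec$rname == refs$name[r] & !is.na(rec$pos)
    if (!any(sel)) {
      out[[r]] <- numeric(n_tiles)
      next
    }
    ir <- IRanges::IRanges(start = rec$pos[sel], width = rec$qwidth[sel])
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(len))
    cov <- IRanges::coverage(ir, width = as.integer(len))
    starts <- seq(1L, len, by = TILE_WIDTH)
    ends <- pmin(starts + TILE_WIDTH - 1L, len)
    vw <- IRanges::Views(cov, start = starts, end = ends)
    out[[r]] <- as.numeric(IRanges::viewMeans(vw))
  }
  if (scaled) {
    all_vals <- unlist(out, use.names = FALSE)
    med <- stats::median(all_vals[all_vals > 0])
    if (is.finite(med) && med > 0) out <- lapply(out, function(v) v / med)
  }
  out
}

#' Byte-truncate an index file
#'
#' Emulates the incompletely written .bai files seen in practice (a
#' classic cause of samples with no apparent coverage): copies the first
#' `fraction` of the file's bytes.
#'
#' @param bai_path Source index.
#' @param out_path Destination.
#' @param fraction Fraction of bytes to keep, in (0, 1).
#' @return `out_path`, invisibly.
#' @export
make_truncated_index <- function(bai_path, out_path, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  n <- file.size(bai_path)
  bytes <- readBin(bai_path, "raw", n = n)
  writeBin(bytes[seq_len(max(1L, floor(n * fraction)))], out_path)
  invisible(out_path)
}

#' Generate a synthetic CRAM index
#'
#' Emits successive slices walking each reference: spans are drawn around
#' `mean_span` and slice byte sizes are Poisson with mean
#' `bytes_per_base * span * mult`, using the same segment multipliers as
#' the BAM generator.  Because no CRAM container encoding is involved, the
#' generator also records its exact total byte count, which tile re-binning
#' must conserve.
#'
#' @param spec A [genome_spec()]; `depth` is reinterpreted through
#'   `bytes_per_base`.
#' @param path Output `.crai` path (gzip TSV), or `NULL` to skip writing.
#' @param mean_span Mean genomic span of a slice, in bases.
#' @param bytes_per_base Expected compressed bytes per covered base at
#'   multiplier 1.
#' @return List with `records` (0-based starts, as [read_crai()] returns)
#'   and `total_bytes`.
#' @export
make_synthetic_crai <- function(spec, path = NULL, mean_span = 3 * TILE_WIDTH,
                                bytes_per_base = 0.3) {
  stopifnot(inherits(spec, "genome_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  rows <- list()
  offset <- 0
  for (r in seq_len(nrow(spec$refs))) {
    len <- spec$refs$length[r]
    iv <- .mult_intervals(spec, spec$refs$name[r])
    pos <- 0
    while (pos < len) {
      span <- min(max(1, round(stats::rexp(1L, 1 / mean_span))), len - pos)
      mid <- pos + span / 2
      mult <- iv$mult[findInterval(mid, iv$start)]
      size <- stats::rpois(1L, bytes_per_base * span * max(mult, 0))
      if (size > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = r - 1L, start = pos, span = span,
          container_offset = offset, slice_offset = 0, slice_size = size)
        offset <- offset + size
      }
      pos <- pos + span
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = integer(0), start = numeric(0), span = numeric(0),
               container_offset = numeric(0), slice_offset = numeric(0),
               slice_size = numeric(0))
  if (!is.null(path)) {
    con <- gzfile(path, "wt")
    writeLines(sprintf("%d\t%d\t%d\t%d\t%d\t%d",
                       records$seq_id, as.integer(records$start) + 1L,
                       as.integer(records$span),
                       as.integer(records$container_offset),
                       as.integer(records$slice_offset),
                       as.integer(records$slice_size)), con)
    close(con)
  }
  list(records = records, total_bytes = sum(records$slice_size))
}

#' Write a FASTA index for a reference table
#'
#' @param refs Data.frame with `name` and `length`.
#' @param path Output `.fai` path.
#' @return `path`, invisibly.
#' @export
write_fai <- function(refs, path) {
  offsets <- cumsum(c(0, utils::head(ceiling(refs$length / 60) + refs$length +
                                nchar(refs$name) + 2, -1)))
  writeLines(sprintf("%s\t%d\t%d\t60\t61", refs$name,
                     as.integer(refs$length), as.integer(offsets)), path)
  invisible(path)
}
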