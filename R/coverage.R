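#' Estimate per-tile byte sizes from a BAM linear index
#'
#' The linear index stores, for each 16384-bp tile, the virtual offset of
#' the first alignment overlapping it.  Each offset is mapped to a scalar
#' file position `coffset + uoffset / 65536` (compressed bytes with a
#' fractional within-block part, preserving monotonicity), and the size of
#' tile *i* is the difference between positions *i+1* and *i* -- the number
#' of compressed bytes the tile's alignments occupy, a proxy for its read
#' depth.  Zero offsets occurring after data has started (tiles the indexer
#' skipped) are fill-forward corrected first.  The last indexed tile and any
#' tiles beyond the linear index get size 0; negative differences from a
#' corrupt index clamp to 0 with a warning.
#'
#' @param bai A `bai_index` from [read_bai()].
#' @param refs Reference table from [read_bam_references()].
#' @return A named list (one element per reference, in `refs` order) of
#'   non-negative numeric vectors, each of length `ceiling(length / 16384)`.
#'   A truncated index yields all-zero sizes for every reference.
#' @export
tile_byte_sizes <- function(bai, refs) {
  n_tiles <- ceiling(refs$length / TILE_WIDTH)
  sizes <- lapply(n_tiles, numeric)
  names(sizes) <- refs$name
  if (isTRUE(bai$truncated)) {
    return(sizes)
  }
  if (bai$n_ref < nrow(refs)) {
    stop("BAI declares ", bai$n_ref, " references but the header has ",
         nrow(refs))
  }
  neg <- FALSE
  for (r in seq_len(nrow(refs))) {
    io <- bai$refs[[r]]
    if (length(io$coffset) < 2L) next
    pos <- io$coffset + io$uoffset / 65536
    pos <- .fill_forward_zeros(pos)
    d <- diff(pos)
    if (any(d < 0)) {
      neg <- TRUE
      d[d < 0] <- 0
    }
    k <- min(length(d), n_tiles[r])
    if (k > 0L) sizes[[r]][seq_len(k)] <- d[seq_len(k)]
  }
  if (neg) {
    warning("linear index contains decreasing offsets (corrupt index?); ",
            "negative tile sizes clamped to 0")
  }
  sizes
}

# Replace zero entries occurring after the first nonzero entry with the
# previous entry (last observation carried forward).
.fill_forward_zeros <- function(pos) {
  nz <- which(pos > 0)
  if (length(nz) == 0L) return(pos)
  first <- nz[1L]
  if (first < length(pos)) {
    tail_part <- pos[first:length(pos)]
    keep <- tail_part > 0
    pos[first:length(pos)] <- tail_part[keep][cumsum(keep)]
  }
  pos
}

#' Re-bin CRAM index slices onto 16384-bp tiles
#'
#' CRAI slices have sample-specific genomic spans, so their byte sizes are
#' redistributed onto the fixed tile grid: each slice's bytes are split
#' across the tiles overlapped by `[start, start + span)` proportionally to
#' the overlap length.  Total bytes are conserved exactly (up to float
#' round-off).
#'
#' @param records Data.frame from [read_crai()] (0-based starts).
#' @param fai Data.frame from [read_fai()]; row order maps `seq_id` to a
#'   reference.
#' @return Named list of per-tile byte vectors, as in [tile_byte_sizes()].
#' @export
crai_tile_sizes <- function(records, fai) {
  n_tiles <- ceiling(fai$length / TILE_WIDTH)
  sizes <- lapply(n_tiles, numeric)
  names(sizes) <- fai$name
  if (nrow(records) == 0L) return(sizes)
  if (any(records$seq_id < 0L) || any(records$seq_id >= nrow(fai))) {
    stop("CRAI seq_id out of range for the supplied FAI (",
         nrow(fai), " references)")
  }
  for (i in seq_len(nrow(records))) {
    r <- records$seq_id[i] + 1L
    start <- records$start[i]
    span <- records$span[i]
    bytes <- records$slice_size[i]
    if (bytes <= 0) next
    nt <- n_tiles[r]
    if (span <= 0) {
      t0 <- min(start %/% TILE_WIDTH + 1, nt)
      sizes[[r]][t0] <- sizes[[r]][t0] + bytes
      next
    }
    end <- start + span
    t0 <- start %/% TILE_WIDTH
    t1 <- (end - 1) %/% TILE_WIDTH
    tt <- t0:t1
    ov <- pmin(end, (tt + 1) * TILE_WIDTH) - pmax(start, tt * TILE_WIDTH)
    # slices running past the reference end keep their bytes in the last tile
    tt <- pmin(tt + 1, nt)
    frac <- bytes * ov / span
    for (j in seq_along(tt)) {
      sizes[[r]][tt[j]] <- sizes[[r]][tt[j]] + frac[j]
    }
  }
  sizes
}

# TRUE for reference names that designate sex chromosomes, tolerant of a
# "chr" prefix on either side.
is_sex_chrom <- function(names, sex_chroms = c("X", "Y")) {
  sub("^chr", "", names) %in% sub("^chr", "", sex_chroms)
}

#' Genome-wide baseline byte size
#'
#' The baseline is the median of the nonzero tile byte sizes over autosomal
#' (non-excluded, non-sex) references.  Zero tiles are left out because
#' N-masked assembly gaps (centromeres, acrocentric arms) would bias the
#' median downward; sex chromosomes are left out because their dosage
#' differs between males and females while the baseline must represent the
#' diploid state.
#'
#' @param sizes Per-reference tile byte sizes ([tile_byte_sizes()]).
#' @param refs Reference table.
#' @param sex_chroms Sex-chromosome names (default X and Y, "chr" prefix
#'   optional).
#' @return The baseline byte value; 0 when no qualifying tile exists (the
#'   sample should then be flagged rather than scaled).
#' @export
compute_baseline <- function(sizes, refs, sex_chroms = c("X", "Y")) {
  use <- !refs$excluded & !is_sex_chrom(refs$name, sex_chroms)
  vals <- unlist(sizes[use], use.names = FALSE)
  vals <- vals[vals > 0]
  if (length(vals) == 0L) return(0)
  stats::median(vals)
}

#' Scale tile byte sizes to relative coverage
#'
#' Dividing each tile's byte size by the genome-wide baseline gives a
#' dimensionless relative coverage where 1.0 is the diploid baseline, 0.5
#' suggests a hemizygous deletion, 1.5 a duplication.  No clipping is
#' applied at this stage.
#'
#' @param sizes Per-reference tile byte sizes.
#' @param baseline Baseline from [compute_baseline()]; when 0 the profile is
#'   all zeros and flagged.
#' @param sample_id Sample identifier carried through to outputs.
#' @return A `coverage_profile` object: list with `sample_id`, `scaled`
#'   (named list of per-reference numeric vectors), `baseline`, `flagged`.
#' @export
scale_profile <- function(sizes, baseline, sample_id = "sample") {
  stopifnot(baseline >= 0)
  scaled <- if (baseline > 0) {
    lapply(sizes, function(v) v / baseline)
  } else {
    lapply(sizes, function(v) numeric(length(v)))
  }
  structure(
    list(sample_id = sample_id, scaled = scaled, baseline = baseline,
         flagged = baseline <= 0),
    class = "coverage_profile"
  )
}

#' Quantize scaled coverage to one byte
#'
#' The cohort matrix used for PCA stores each scaled value in a single byte:
#' `round(value * 64)` clamped to \[0, 255\], i.e. a resolution of 1/64 and
#' saturation at 255/64 (scaled coverage of about 3.98, copy number 8).  The
#' precision loss is irrelevant for the large deviations the QC targets.
#'
#' @param value Non-negative scaled coverage values.
#' @return Integer codes in \[0, 255\].
#' @seealso [dequantize_scaled()]
#' @export
quantize_scaled <- function(value) {
  stopifnot(all(value >= 0))
  as.integer(pmin(pmax(round(value * 64), 0), 255))
}

#' @rdname quantize_scaled
#' @param code Integer codes in \[0, 255\].
#' @export
dequantize_scaled <- function(code) {
  code / 64
}

#' Assemble the cohort coverage matrix
#'
#' Concatenates each sample's scaled tiles over the non-excluded references
#' (reference order, then tile order) and quantizes them to one byte per
#' entry.
#'
#' @param profiles List of `coverage_profile` objects sharing one tile grid.
#' @param refs Reference table; excluded references are dropped.
#' @return A `cohort_matrix`: list with `matrix` (samples x tiles, integer
#'   codes), `tiles` (data.frame `chrom`, `start`, `end`, 0-based
#'   half-open), and `samples`.
#' @export
build_cohort_matrix <- function(profiles, refs) {
  keep <- refs[!refs$excluded, , drop = FALSE]
  tiles <- tile_table(keep)
  samples <- vapply(profiles, `[[`, "", "sample_id")
  mat <- matrix(0L, nrow = length(profiles), ncol = nrow(tiles),
                dimnames = list(samples, NULL))
  for (i in seq_along(profiles)) {
    v <- unlist(profiles[[i]]$scaled[keep$name], use.names = FALSE)
    if (length(v) != ncol(mat)) {
      stop("sample '", samples[i], "' has ", length(v),
           " tiles; expected ", ncol(mat))
    }
    mat[i, ] <- quantize_scaled(v)
  }
  structure(list(matrix = mat, tiles = tiles, samples = samples),
            class = "cohort_matrix")
}

#' Tile coordinate table for a set of references
#'
#' @param refs Reference table (already subset as desired).
#' @return Data.frame `chrom`, `start`, `end` with 0-based half-open
#'   16384-bp tiles, the final tile truncated to the reference length.
#' @export
tile_table <- function(refs) {
  pieces <- lapply(seq_len(nrow(refs)), function(r) {
    len <- refs$length[r]
    start <- seq(0, len - 1, by = TILE_WIDTH)
    data.frame(chrom = refs$name[r], start = start,
               end = pmin(start + TILE_WIDTH, len))
  })
  do.call(rbind, pieces)
}
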