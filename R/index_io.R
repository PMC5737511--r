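# Width of one coverage tile in bases.  This is fixed by the BAI format: the
# linear index stores one virtual offset per 16384-bp window.
TILE_WIDTH <- 16384L

#' Default chromosome-exclusion pattern
#'
#' Regular expression matched against reference names; matching contigs
#' (decoys, alternate haplotypes, unplaced scaffolds) are flagged `excluded`
#' and kept out of the genome-wide median, the tile statistics and the
#' report.  They would otherwise drag the coverage baseline down.
#'
#' @return A character scalar (a PCRE-style regex).
#' @export
default_exclude_pattern <- function() {
  "_random$|_alt$|^chrUn|^GL|^NC_|^hs37d5$|^HLA-|hap\\d+$|^chrEBV$"
}

#' Split a BGZF virtual offset into its two components
#'
#' A virtual offset is a 64-bit pointer used by BGZF-backed indexes: the
#' upper 48 bits give the byte offset of a compressed block within the file
#' (`coffset`), the lower 16 bits the offset within that block's
#' uncompressed data (`uoffset`), so `raw == coffset * 2^16 + uoffset`.
#'
#' @param raw Numeric vector of non-negative virtual offsets.  Values are
#'   held as doubles; offsets are exact up to 2^53, far beyond any real
#'   index (a coffset of 2^37 already addresses a 128 GiB file).
#' @return A data.frame with columns `raw`, `coffset`, `uoffset`.
#' @examples
#' split_virtual_offset(65536)   # coffset 1, uoffset 0
#' @export
split_virtual_offset <- function(raw) {
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("virtual offsets must be finite and non-negative")
  }
  coffset <- floor(raw / 65536)
  uoffset <- raw - coffset * 65536
  data.frame(raw = raw, coffset = coffset, uoffset = uoffset)
}

# Decode n little-endian 64-bit virtual offsets from a raw vector slice.
# Returns list(coffset=, uoffset=) as doubles; avoids composing the full
# 64-bit value so precision is never lost.
.decode_voffsets <- function(bytes) {
  stopifnot(length(bytes) %% 8L == 0L)
  if (length(bytes) == 0L) {
    return(list(coffset = numeric(0), uoffset = numeric(0)))
  }
  m <- matrix(as.integer(bytes), nrow = 8L)
  list(
    coffset = m[3L, ] + m[4L, ] * 2^8 + m[5L, ] * 2^16 +
      m[6L, ] * 2^24 + m[7L, ] * 2^32 + m[8L, ] * 2^40,
    uoffset = m[1L, ] + m[2L, ] * 256
  )
}

# Little-endian int32 (signed) at byte position pos (1-based).
.decode_int32 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 3L)], "integer", n = 1L, size = 4L,
          endian = "little")
}

# Little-endian unsigned 64-bit as double.
.decode_uint64 <- function(bytes, pos) {
  b <- as.integer(bytes[pos:(pos + 7L)])
  sum(b * 2^(8 * (0:7)))
}

#' Read reference names and lengths from a BAM header
#'
#' The BAI itself stores no reference names, so they are taken from the BAM
#' header (`@SQ` lines), in file order -- that order defines the reference
#' ordinals used by the index.
#'
#' @param bam_path Path to a coordinate-sorted BAM file.
#' @param exclude Regex applied to reference names; matches get
#'   `excluded = TRUE`.  `NULL` or `""` disables exclusion.
#' @return A data.frame with columns `name`, `length`, `excluded`.
#' @export
read_bam_references <- function(bam_path, exclude = default_exclude_pattern()) {
  if (!file.exists(bam_path)) {
    stop("BAM file not found: ", bam_path)
  }
  hdr <- tryCatch(
    Rsamtools::scanBamHeader(bam_path)[[1L]],
    error = function(e) stop("cannot read BAM header from '", bam_path,
                             "': ", conditionMessage(e))
  )
  targets <- hdr$targets
  if (length(targets) == 0L) {
    warning("BAM header of '", bam_path, "' declares no references")
    return(data.frame(name = character(0), length = integer(0),
                      excluded = logical(0)))
  }
  .make_references(names(targets), unname(as.numeric(targets)), exclude)
}

.make_references <- function(names, lengths, exclude) {
  if (anyDuplicated(names)) {
    stop("duplicate reference names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (any(lengths <= 0)) stop("reference lengths must be positive")
  excl <- if (is.null(exclude) || !nzchar(exclude)) {
    rep(FALSE, length(names))
  } else {
    grepl(exclude, names, perl = TRUE)
  }
  data.frame(name = names, length = as.numeric(lengths), excluded = excl,
             stringsAsFactors = FALSE)
}

#' Read a BAM index (.bai) file
#'
#' Parses the binary BAI layout: per reference a set of R-tree bins
#' (skipped, except the metadata pseudo-bin 37450, whose mapped/unmapped
#' record counts are kept) followed by the linear index -- one virtual
#' offset per 16384-bp tile, pointing at the first alignment overlapping
#' that tile.  Only the linear index and the counts are retained.
#'
#' A stream that ends before `n_expected_refs` references have been read, or
#' mid-structure, yields `truncated = TRUE` with a warning rather than an
#' error: a truncated index is a QC finding, and the sample must still
#' surface (flagged) in cohort outputs.
#'
#' @param bai_path Path to the .bai file.
#' @param n_expected_refs Number of references declared by the BAM header,
#'   or `NULL` to trust the BAI's own count.
#' @return An object of class `bai_index`: a list with elements `n_ref`,
#'   `truncated`, and `refs` -- one entry per reference, each holding
#'   `coffset`/`uoffset` numeric vectors (the linear index) and
#'   `n_mapped`/`n_unmapped` counts (`NA` when pseudo-bin 37450 is absent).
#' @export
read_bai <- function(bai_path, n_expected_refs = NULL) {
  if (!file.exists(bai_path)) stop("BAI file not found: ", bai_path)
  bytes <- readBin(bai_path, "raw", n = file.size(bai_path))
  n <- length(bytes)
  if (n < 4L || rawToChar(bytes[1:3]) != "BAI" || as.integer(bytes[4L]) != 1L) {
    stop("'", bai_path, "' is not a BAI file (bad magic)")
  }

  truncated <- FALSE
  pos <- 5L
  avail <- function(k) pos + k - 1L <= n

  if (!avail(4L)) {
    truncated <- TRUE
    n_ref <- 0L
  } else {
    n_ref <- .decode_int32(bytes, pos)
    pos <- pos + 4L
  }

  empty_ref <- function() {
    list(coffset = numeric(0), uoffset = numeric(0),
         n_mapped = NA_real_, n_unmapped = NA_real_)
  }
  refs <- vector("list", n_ref)

  for (r in seq_len(n_ref)) {
    refs[[r]] <- empty_ref()
    if (truncated) next
    if (!avail(4L)) { truncated <- TRUE; next }
    n_bin <- .decode_int32(bytes, pos); pos <- pos + 4L
    for (b in seq_len(n_bin)) {
      if (!avail(8L)) { truncated <- TRUE; break }
      bin_no <- .decode_int32(bytes, pos)  # uint32 in the format; all real bins < 2^31

      n_chunk <- .decode_int32(bytes, pos + 4L)
      pos <- pos + 8L
      if (!avail(16L * n_chunk)) { truncated <- TRUE; break }
      if (bin_no == 37450L && n_chunk == 2L) {
        # chunk 1: unmapped-region virtual offsets; chunk 2: record counts
        refs[[r]]$n_mapped   <- .decode_uint64(bytes, pos + 16L)
        refs[[r]]$n_unmapped <- .decode_uint64(bytes, pos + 24L)
      }
      pos <- pos + 16L * n_chunk
    }
    if (truncated) next
    if (!avail(4L)) { truncated <- TRUE; next }
    n_intv <- .decode_int32(bytes, pos); pos <- pos + 4L
    if (!avail(8L * n_intv)) { truncated <- TRUE; next }
    if (n_intv > 0L) {
      vo <- .decode_voffsets(bytes[pos:(pos + 8L * n_intv - 1L)])
      refs[[r]]$coffset <- vo$coffset
      refs[[r]]$uoffset <- vo$uoffset
    }
    pos <- pos + 8L * n_intv
  }

  if (!is.null(n_expected_refs) && n_ref < n_expected_refs) {
    truncated <- TRUE
    refs <- c(refs, replicate(n_expected_refs - n_ref, empty_ref(),
                              simplify = FALSE))
  }
  if (truncated) {
    warning("BAI index '", bai_path, "' is truncated; sample will be ",
            "flagged with an all-zero coverage profile")
  }
  structure(list(n_ref = length(refs), truncated = truncated, refs = refs),
            class = "bai_index")
}

#' Read a CRAM index (.crai) file
#'
#' A .crai is gzip-compressed text with one slice per line and six
#' tab-separated integer fields: reference ordinal (0-based; -1 for
#' unmapped), 1-based alignment start, span in bases, container byte
#' offset, slice byte offset within the container, and slice size in bytes.
#' Unmapped records are dropped; starts are converted to 0-based on read.
#'
#' @param crai_path Path to the .crai file.
#' @return A data.frame with columns `seq_id`, `start` (0-based), `span`,
#'   `container_offset`, `slice_offset`, `slice_size`.
#' @export
read_crai <- function(crai_path) {
  if (!file.exists(crai_path)) stop("CRAI file not found: ", crai_path)
  con <- gzfile(crai_path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("CRAI file '", crai_path, "' contains no records")
    return(data.frame(seq_id = integer(0), start = numeric(0),
                      span = numeric(0), container_offset = numeric(0),
                      slice_offset = numeric(0), slice_size = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    stop("malformed CRAI line ", which(nf != 6L)[1L], " in '", crai_path,
         "': expected 6 tab-separated fields, found ", nf[nf != 6L][1L])
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(parts, use.names = FALSE)), ncol = 6L,
           byrow = TRUE)
  )
  if (anyNA(m)) {
    stop("malformed CRAI line ", which(rowSums(is.na(m)) > 0)[1L], " in '",
         crai_path, "': non-integer field")
  }
  if (any(m[, 3L] < 0) || any(m[, 6L] < 0)) {
    stop("malformed CRAI file '", crai_path,
         "': negative span or slice size")
  }
  keep <- m[, 1L] >= 0
  data.frame(
    seq_id = as.integer(m[keep, 1L]),
    start = m[keep, 2L] - 1,        # to 0-based
    span = m[keep, 3L],
    container_offset = m[keep, 4L],
    slice_offset = m[keep, 5L],
    slice_size = m[keep, 6L]
  )
}

#' Read a FASTA index (.fai) file
#'
#' Only the first two columns (reference name, length) are used.  Row order
#' defines the `seq_id` mapping used by CRAI records: seq_id `i` is row
#' `i + 1`.
#'
#' @param fai_path Path to the .fai file.
#' @return A data.frame with columns `name` and `length`.
#' @export
read_fai <- function(fai_path) {
  if (!file.exists(fai_path)) stop("FAI file not found: ", fai_path)
  lines <- readLines(fai_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("FAI file '", fai_path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("malformed FAI line ", which(lengths(parts) < 2L)[1L], " in '",
         fai_path, "': need at least name and length columns")
  }
  name <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len) || any(len <= 0)) {
    stop("malformed FAI file '", fai_path, "': bad length column")
  }
  data.frame(name = name, length = len, stringsAsFactors = FALSE)
}

#' Build a reference table from a FASTA index
#'
#' @param fai A data.frame as returned by [read_fai()].
#' @param exclude Regex of reference names to flag as excluded.
#' @return A data.frame with columns `name`, `length`, `excluded`.
#' @export
fai_references <- function(fai, exclude = default_exclude_pattern()) {
  .make_references(fai$name, fai$length, exclude)
}
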