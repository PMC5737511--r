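# Shared synthetic fixtures, built lazily once per test run and cached in
# a session-level temp directory.

.fix <- new.env(parent = emptyenv())

fixture_dir <- function() {
  if (is.null(.fix$dir)) {
    .fix$dir <- file.path(tempdir(), "idxcov-fixtures")
    dir.create(.fix$dir, showWarnings = FALSE, recursive = TRUE)
  }
  .fix$dir
}

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# Two-reference genome with one excluded decoy contig; moderate size so the
# BAI has a real multi-tile linear index.
toy_refs <- function() {
  data.frame(name = c("chr1", "chrX", "chr1_random"),
             length = c(2e6, 1e6, 5e4))
}

# Uniform-coverage BAM over toy_refs (decoy left empty).
toy_bam <- function() {
  cached("toy_bam", {
    sp <- genome_spec(toy_refs(),
                      segments = data.frame(ref = "chr1_random", start = 0,
                                            end = 5e4, mult = 0),
                      depth = 8, read_length = 150L, seed = 7L)
    path <- file.path(fixture_dir(), "toy.bam")
    res <- make_synthetic_bam(sp, path)
    res$spec <- sp
    res
  })
}

# BAM with no alignments at all.
empty_bam <- function() {
  cached("empty_bam", {
    sp <- genome_spec(data.frame(name = c("c1", "c2"), length = c(1e5, 8e4)),
                      segments = data.frame(ref = c("c1", "c2"), start = 0,
                                            end = c(1e5, 8e4), mult = 0),
                      depth = 5, read_length = 100L, seed = 3L)
    res <- make_synthetic_bam(sp, file.path(fixture_dir(), "empty.bam"))
    res$spec <- sp
    res
  })
}

# Small sex cohort: autosome chr1 at full density everywhere; X/Y densities
# chosen per sample to emulate female (XX), male (XY), XYY and X-trisomy
# karyotypes at 10x equivalent depth.
sex_cohort_refs <- function() {
  data.frame(name = c("chr1", "chrX", "chrY"),
             length = c(2.5e6, 2e6, 1.5e6))
}

sex_cohort <- function() {
  cached("sex_cohort", {
    plan <- list(
      female = c(X = 1, Y = 0),
      male = c(X = 0.5, Y = 0.5),
      xyy = c(X = 0.5, Y = 1),
      xxx = c(X = 1.5, Y = 0)
    )
    refs <- sex_cohort_refs()
    paths <- character(length(plan))
    for (i in seq_along(plan)) {
      segs <- data.frame(ref = c("chrX", "chrY"), start = 0,
                         end = c(2e6, 1.5e6), mult = unname(plan[[i]]))
      sp <- genome_spec(refs, segs, depth = 10, read_length = 1000L,
                        seed = 200L + i)
      paths[i] <- file.path(fixture_dir(),
                            sprintf("sex_%s.bam", names(plan)[i]))
      make_synthetic_bam(sp, paths[i])
    }
    list(paths = paths, karyotypes = names(plan), refs = refs)
  })
}

# Pipeline results for the sex cohort (shared across qc/report/cli tests).
sex_cohort_run <- function() {
  cached("sex_cohort_run", {
    co <- sex_cohort()
    out <- file.path(fixture_dir(), "sex_out")
    run_indexcov(co$paths, out, deterministic_html = TRUE)
  })
}

# Hand-built bai_index object (no file involved).
fake_bai <- function(coffsets, uoffsets = NULL, n_ref = 1L,
                     truncated = FALSE) {
  if (!is.list(coffsets)) coffsets <- list(coffsets)
  if (is.null(uoffsets)) uoffsets <- lapply(coffsets, function(x) x * 0)
  if (!is.list(uoffsets)) uoffsets <- list(uoffsets)
  refs <- lapply(seq_len(n_ref), function(r) {
    list(coffset = if (r <= length(coffsets)) coffsets[[r]] else numeric(0),
         uoffset = if (r <= length(uoffsets)) uoffsets[[r]] else numeric(0),
         n_mapped = NA_real_, n_unmapped = NA_real_)
  })
  structure(list(n_ref = n_ref, truncated = truncated, refs = refs),
            class = "bai_index")
}

# Coverage profile built directly from scaled values.
fake_profile <- function(scaled, sample_id = "s1", baseline = 1000) {
  structure(list(sample_id = sample_id, scaled = scaled,
                 baseline = baseline, flagged = baseline <= 0),
            class = "coverage_profile")
}
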