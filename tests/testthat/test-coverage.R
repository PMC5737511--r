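test_that("tile byte sizes follow differences of linear-index positions", {
  refs <- data.frame(name = "c1", length = 5 * 16384, excluded = FALSE)

  # identical consecutive offsets: zero-size first tile
  bai <- fake_bai(c(100, 100))
  expect_equal(tile_byte_sizes(bai, refs)$c1, c(0, 0, 0, 0, 0))

  # constant compressed step of 32768 bytes per tile
  bai <- fake_bai(c(0, 32768, 65536, 98304, 131072))
  expect_equal(tile_byte_sizes(bai, refs)$c1,
               c(32768, 32768, 32768, 32768, 0))

  # within-block offsets contribute fractionally
  bai <- fake_bai(c(100, 100), uoffsets = c(0, 32768))
  expect_equal(tile_byte_sizes(bai, refs)$c1[1], 0.5)

  # tiles beyond the linear index stay zero
  bai <- fake_bai(c(0, 1000))
  expect_equal(tile_byte_sizes(bai, refs)$c1, c(1000, 0, 0, 0, 0))
})

test_that("zero offsets after data starts are filled forward", {
  refs <- data.frame(name = "c1", length = 5 * 16384, excluded = FALSE)
  # leading zeros untouched, interior zero carried forward
  bai <- fake_bai(c(0, 500, 0, 900, 1000))
  expect_equal(tile_byte_sizes(bai, refs)$c1, c(500, 0, 400, 100, 0))
})

test_that("corrupt decreasing offsets clamp to zero with a warning", {
  refs <- data.frame(name = "c1", length = 3 * 16384, excluded = FALSE)
  bai <- fake_bai(c(900, 500, 1000))
  expect_warning(sz <- tile_byte_sizes(bai, refs), "clamped")
  expect_equal(sz$c1, c(0, 500, 0))
})

test_that("truncated indexes give all-zero sizes for every reference", {
  refs <- data.frame(name = c("c1", "c2"), length = c(3, 2) * 16384,
                     excluded = FALSE)
  bai <- fake_bai(list(c(0, 100), c(0, 100)), n_ref = 2L, truncated = TRUE)
  sz <- tile_byte_sizes(bai, refs)
  expect_true(all(unlist(sz) == 0))
  expect_equal(lengths(sz), c(c1 = 3L, c2 = 2L))
})

test_that("tile sizes are invariant to prepending empty references", {
  offs <- c(0, 1000, 2500, 2500, 4000)
  refs1 <- data.frame(name = "cA", length = 5 * 16384, excluded = FALSE)
  refs2 <- data.frame(name = c("empty1", "empty2", "cA"),
                      length = c(16384, 32768, 5 * 16384),
                      excluded = FALSE)
  a <- tile_byte_sizes(fake_bai(offs), refs1)$cA
  b <- tile_byte_sizes(fake_bai(list(numeric(0), numeric(0), offs),
                                n_ref = 3L), refs2)$cA
  expect_identical(a, b)
})

test_that("index-derived coverage tracks the per-base depth oracle", {
  # uniform genome; long fat records keep BGZF block granularity small
  # relative to per-tile bytes (see the methods vignette for the sizing)
  refs <- data.frame(name = c("u1", "u2"), length = c(1.5e6, 1e6))
  sp <- genome_spec(refs, depth = 10, read_length = 2000L,
                    pad_bytes = 12000L, seed = 31L)
  path <- file.path(fixture_dir(), "uniform_fat.bam")
  make_synthetic_bam(sp, path)
  rr <- read_bam_references(path)
  bai <- read_bai(paste0(path, ".bai"), nrow(rr))
  sizes <- tile_byte_sizes(bai, rr)
  prof <- scale_profile(sizes, compute_baseline(sizes, rr))
  oracle <- depth_oracle(path, rr)
  est <- unlist(prof$scaled, use.names = FALSE)
  tru <- unlist(oracle, use.names = FALSE)
  nz <- est > 0 & tru > 0
  expect_gt(sum(nz), 100L)
  expect_gt(cor(est[nz], tru[nz]), 0.95)
})

test_that("CRAI re-binning distributes slice bytes by overlap", {
  fai <- data.frame(name = "c1", length = 10 * 16384)

  # full containment in tile 3
  rec <- data.frame(seq_id = 0L, start = 2 * 16384, span = 16384,
                    container_offset = 0, slice_offset = 0,
                    slice_size = 9000)
  sz <- crai_tile_sizes(rec, fai)$c1
  expect_equal(sz[3], 9000)
  expect_equal(sum(sz), 9000)

  # 8000 bytes spanning two tiles 50/50
  rec <- data.frame(seq_id = 0L, start = 16384 / 2, span = 16384,
                    container_offset = 0, slice_offset = 0,
                    slice_size = 8000)
  sz <- crai_tile_sizes(rec, fai)$c1
  expect_equal(sz[1:2], c(4000, 4000))

  # seq_id out of range is fatal
  expect_error(crai_tile_sizes(data.frame(seq_id = 5L, start = 0, span = 1,
                                          container_offset = 0,
                                          slice_offset = 0, slice_size = 1),
                               fai), "out of range")
})

test_that("CRAI re-binning matches a per-base accumulation oracle", {
  set.seed(41)
  fai <- data.frame(name = c("c1", "c2"), length = c(30 * 16384, 20 * 16384))
  n <- 200L
  seq_id <- sample(0:1, n, replace = TRUE)
  len <- fai$length[seq_id + 1L]
  start <- floor(runif(n) * (len - 1))
  span <- pmin(1 + floor(runif(n) * 40000), len - start)
  rec <- data.frame(seq_id = seq_id, start = start, span = span,
                    container_offset = 0, slice_offset = 0,
                    slice_size = 1 + floor(runif(n) * 10000))
  sz <- crai_tile_sizes(rec, fai)

  # oracle: spread size/span bytes per covered base, then sum per tile
  oracle <- lapply(fai$length, function(l) numeric(ceiling(l / 16384)))
  names(oracle) <- fai$name
  for (i in seq_len(n)) {
    r <- rec$seq_id[i] + 1L
    bases <- rec$start[i]:(rec$start[i] + rec$span[i] - 1)
    per_base <- rec$slice_size[i] / rec$span[i]
    tl <- tabulate(bases %/% 16384 + 1,
                   nbins = length(oracle[[r]]))
    oracle[[r]] <- oracle[[r]] + tl * per_base
  }
  expect_equal(sz$c1, oracle$c1, tolerance = 1e-9)
  expect_equal(sz$c2, oracle$c2, tolerance = 1e-9)

  # byte conservation to 1e-6 relative tolerance
  expect_equal(sum(unlist(sz)), sum(rec$slice_size), tolerance = 1e-6)
})

test_that("baseline is the median nonzero autosomal tile size", {
  refs <- data.frame(name = c("c1", "chrX"), length = c(21, 5) * 16384,
                     excluded = FALSE)

  sizes <- list(c1 = rep(32768, 21), chrX = rep(1, 5))
  expect_equal(compute_baseline(sizes, refs), 32768)

  # median of {16384 x10, 32768 x11} is 32768
  sizes <- list(c1 = c(rep(16384, 10), rep(32768, 11)), chrX = rep(1, 5))
  expect_equal(compute_baseline(sizes, refs), 32768)

  # zero tiles are excluded from the median
  sizes <- list(c1 = c(rep(0, 15), rep(100, 6)), chrX = rep(1, 5))
  expect_equal(compute_baseline(sizes, refs), 100)

  # sex chromosomes never move the baseline
  sizes_a <- list(c1 = rep(50, 21), chrX = rep(999, 5))
  sizes_b <- list(c1 = rep(50, 21), chrX = rep(0, 5))
  expect_equal(compute_baseline(sizes_a, refs),
               compute_baseline(sizes_b, refs))

  # excluded contigs never move the baseline
  refs2 <- data.frame(name = c("c1", "decoy"), length = c(21, 5) * 16384,
                      excluded = c(FALSE, TRUE))
  expect_equal(compute_baseline(list(c1 = rep(50, 21), decoy = rep(9e6, 5)),
                                refs2), 50)

  # no qualifying tile: baseline 0 (sample to be flagged)
  expect_equal(compute_baseline(list(c1 = rep(0, 21), chrX = rep(3, 5)),
                                refs), 0)
})

test_that("scaling maps the baseline to 1 and zero baseline to flagged", {
  sizes <- list(c1 = c(1000, 500, 0, 2000))
  p <- scale_profile(sizes, 1000, "s")
  expect_equal(p$scaled$c1, c(1, 0.5, 0, 2))
  expect_false(p$flagged)

  p0 <- scale_profile(sizes, 0, "s")
  expect_true(p0$flagged)
  expect_true(all(p0$scaled$c1 == 0))
})

test_that("median of scaled values over baseline-defining tiles is 1", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sizes <- list(c1 = round(rgamma(n, 10, 0.01)))
    refs <- data.frame(name = "c1", length = n * 16384, excluded = FALSE)
    b <- compute_baseline(sizes, refs)
    p <- scale_profile(sizes, b)
    v <- p$scaled$c1[sizes$c1 > 0]
    expect_equal(median(v), 1.0)
  }
})

test_that("one-byte quantization has 1/64 resolution and saturates", {
  expect_identical(quantize_scaled(0), 0L)
  expect_identical(quantize_scaled(1), 64L)
  expect_identical(quantize_scaled(10), 255L)
  v <- seq(0, 3.9, by = 0.013)
  q <- quantize_scaled(v)
  expect_true(all(q >= 0L & q <= 255L))
  expect_true(all(abs(dequantize_scaled(q) - v) <= 1 / 128 + 1e-12))
  expect_error(quantize_scaled(-0.1))
})

test_that("cohort matrix concatenates tiles in reference order", {
  refs <- data.frame(name = c("c1", "c2", "bad_random"),
                     length = c(2.5, 1.5, 1) * 16384,
                     excluded = c(FALSE, FALSE, TRUE))
  p1 <- fake_profile(list(c1 = c(1, 0.5, 2), c2 = c(1, 1),
                          bad_random = 9), "a")
  p2 <- fake_profile(list(c1 = c(0, 1, 1), c2 = c(0.25, 4),
                          bad_random = 9), "b")
  cm <- build_cohort_matrix(list(p1, p2), refs)
  expect_equal(dim(cm$matrix), c(2L, 5L))
  expect_equal(cm$matrix["a", ], quantize_scaled(c(1, 0.5, 2, 1, 1)))
  expect_equal(cm$matrix["b", ], quantize_scaled(c(0, 1, 1, 0.25, 4)))
  expect_equal(cm$tiles$chrom, c("c1", "c1", "c1", "c2", "c2"))
  expect_equal(cm$tiles$start[1:3], c(0, 16384, 32768))
  # final tile truncated to the reference length
  expect_equal(cm$tiles$end[3], 2.5 * 16384)
})
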