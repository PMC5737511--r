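#' Usable-tile masks for a cohort
#'
#' Tiles with zero scaled coverage in every sample carry no information
#' about any sample: they are almost always N-masked reference gaps
#' (centromeres, acrocentric arms) and are excluded from tile statistics,
#' PCA and copy-number estimation.  With a single sample there is no
#' cohort to vote, so a run of >= `min_gap_run` consecutive zero tiles is
#' treated as a gap while isolated zero tiles count as genuinely missing
#' coverage.
#'
#' @param profiles List of `coverage_profile` objects on one tile grid.
#' @param min_gap_run Minimum zero-run length treated as a reference gap in
#'   single-sample mode.
#' @return Named list of logical vectors (TRUE = tile usable), one per
#'   reference present in the profiles.
#' @export
usable_tile_masks <- function(profiles, min_gap_run = 3L) {
  stopifnot(length(profiles) >= 1L)
  ref_names <- names(profiles[[1L]]$scaled)
  if (length(profiles) > 1L) {
    masks <- lapply(ref_names, function(rn) {
      any_nz <- Reduce(`|`, lapply(profiles, function(p) p$scaled[[rn]] > 0))
      any_nz
    })
  } else {
    masks <- lapply(ref_names, function(rn) {
      v <- profiles[[1L]]$scaled[[rn]]
      zero <- v == 0
      r <- rle(zero)
      gap <- rep(r$values & r$lengths >= min_gap_run, r$lengths)
      !gap
    })
  }
  names(masks) <- ref_names
  masks
}

#' Estimate the copy number of a chromosome
#'
#' Copy number is twice the median scaled coverage of the chromosome's
#' usable tiles: scaled coverage 1.0 corresponds to the diploid (CN 2)
#' autosomal baseline, so a male X at half depth gives CN 1.  The median,
#' not the mean, is used so that segmental CNVs on the chromosome do not
#' shift the estimate.  Flagged samples (zero baseline, e.g. a truncated
#' index) return 0.
#'
#' @param profile A `coverage_profile`.
#' @param chrom_name Chromosome to estimate.
#' @param mask Logical vector of usable tiles for that chromosome
#'   ([usable_tile_masks()]); `NULL` uses all tiles.
#' @return Estimated copy number (non-negative real).
#' @export
estimate_copy_number <- function(profile, chrom_name, mask = NULL) {
  vals <- profile$scaled[[chrom_name]]
  if (is.null(vals)) {
    stop("chromosome '", chrom_name, "' not in profile; available: ",
         paste(names(profile$scaled), collapse = ", "))
  }
  if (isTRUE(profile$flagged)) return(0)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(vals))
    vals <- vals[mask]
  }
  if (length(vals) == 0L) return(0)
  2 * stats::median(vals)
}

#' Infer sample sex from the X copy number
#'
#' A step rule with thresholds placed between the integer copy-number
#' states seen in real cohorts: CN X below 0.4 is called unknown (a dead
#' zone capturing broken samples, e.g. truncated indexes, which sit near
#' the origin), CN X in \[0.4, 1.5) male, CN X >= 1.5 female.
#'
#' @param cn_x Estimated X copy number (>= 0).
#' @return List with `sex_label` ("male", "female" or "unknown") and
#'   `ped_sex_code` (1, 2 or 0, the PED convention).
#' @export
infer_sex <- function(cn_x) {
  stopifnot(is.finite(cn_x), cn_x >= 0)
  if (cn_x < 0.4) {
    list(sex_label = "unknown", ped_sex_code = 0L)
  } else if (cn_x < 1.5) {
    list(sex_label = "male", ped_sex_code = 1L)
  } else {
    list(sex_label = "female", ped_sex_code = 2L)
  }
}

#' Tile-proportion anomaly statistics
#'
#' Over the evaluated (usable autosomal) tiles, computes the proportion
#' with scaled coverage below 0.15 (`p_low`: missing or nearly missing
#' data), inside the closed interval \[0.85, 1.15\] (`p_in`: well-behaved),
#' and outside it (`p_out = 1 - p_in`: biased or variable coverage).  A
#' normal uniformly covered sample has small `p_low` and `p_out`; a dead or
#' truncated sample has `p_low = 1`.
#'
#' @param values Scaled coverage values of the evaluated tiles (already
#'   masked), or a full vector plus `mask`.
#' @param mask Optional logical mask applied to `values`.
#' @return List `p_low`, `p_out`, `p_in`, `n_evaluated`.
#' @export
tile_proportions <- function(values, mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(values))
    values <- values[mask]
  }
  n <- length(values)
  if (n == 0L) {
    warning("no tiles to evaluate; proportions set to 0")
    return(list(p_low = 0, p_out = 0, p_in = 0, n_evaluated = 0L))
  }
  p_in <- mean(values >= 0.85 & values <= 1.15)
  list(
    p_low = mean(values < 0.15),
    p_out = 1 - p_in,
    p_in = p_in,
    n_evaluated = n
  )
}

#' Reverse cumulative coverage distribution
#'
#' For each threshold on a fixed grid (0 to 2.5 in steps of 0.02), the
#' proportion of tiles with scaled coverage at or above it.  A clean
#' diploid sample drops steeply through 1.0; high-variance samples have a
#' shallow slope there.
#'
#' @param values Scaled coverage values (finite).
#' @param grid Threshold grid.
#' @return Data.frame `threshold`, `proportion`, non-increasing in
#'   threshold; zero rows for empty input.
#' @export
coverage_cdf <- function(values, grid = seq(0, 2.5, by = 0.02)) {
  stopifnot(all(is.finite(values)))
  if (length(values) == 0L) {
    return(data.frame(threshold = numeric(0), proportion = numeric(0)))
  }
  prop <- vapply(grid, function(t) mean(values >= t), numeric(1))
  data.frame(threshold = grid, proportion = prop)
}

#' Project samples onto principal components of the coverage matrix
#'
#' Works on the dequantized one-byte cohort matrix: all-zero tile columns
#' are removed, the remaining columns are centered by their cohort mean
#' (not scaled -- every column is already on the common scaled-coverage
#' scale), and the top five components are extracted by singular value
#' decomposition.  Signs are fixed so that each component's
#' largest-magnitude tile loading is positive, making the projection
#' deterministic.
#'
#' @param cohort A `cohort_matrix` from [build_cohort_matrix()].
#' @param n_comp Maximum number of components (default 5).
#' @return A `pca_result`: list with `coords` (samples x k matrix, columns
#'   PC1..PCk), `explained` (variance fractions, non-increasing) and
#'   `samples`.  With fewer than two samples, a zero-component result with
#'   a warning.
#' @export
pca_project <- function(cohort, n_comp = 5L) {
  samples <- cohort$samples
  n <- nrow(cohort$matrix)
  if (n < 2L) {
    warning("PCA needs at least 2 samples; returning empty result")
    return(structure(
      list(coords = matrix(0, n, 0, dimnames = list(samples, NULL)),
           explained = numeric(0), samples = samples),
      class = "pca_result"
    ))
  }
  x <- dequantize_scaled(cohort$matrix)
  x <- x[, colSums(x) > 0, drop = FALSE]
  k <- min(n_comp, n - 1L, ncol(x))
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- svd(xc)
  # deterministic orientation: largest-|loading| positive per component
  for (j in seq_len(k)) {
    flip <- s$v[which.max(abs(s$v[, j])), j] < 0
    if (flip) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  coords <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], nrow = k)
  dimnames(coords) <- list(samples, paste0("PC", seq_len(k)))
  explained <- if (sum(s$d^2) > 0) s$d[seq_len(k)]^2 / sum(s$d^2)
               else numeric(k)
  structure(list(coords = coords, explained = explained, samples = samples),
            class = "pca_result")
}

#' Per-sample QC summary for a cohort
#'
#' Combines sex-chromosome copy numbers, the sex call, tile-proportion
#' statistics over usable autosomal tiles, and PC coordinates into one
#' record per sample.
#'
#' @param profiles List of `coverage_profile` objects.
#' @param refs Reference table.
#' @param pca A `pca_result` (or `NULL`).
#' @param sex_chroms Sex-chromosome names.
#' @param masks Usable-tile masks ([usable_tile_masks()]); computed when
#'   `NULL`.
#' @return Data.frame with one row per sample: `sample_id`, `CN<chrom>`
#'   columns, `sex_label`, `ped_sex_code`, `bins_in`, `bins_out`,
#'   `bins_low`, `PC1`..`PC5`, `truncated`.
#' @export
cohort_qc <- function(profiles, refs, pca = NULL,
                      sex_chroms = c("X", "Y"), masks = NULL) {
  if (is.null(masks)) masks <- usable_tile_masks(profiles)
  autosomal <- refs$name[!refs$excluded &
                           !is_sex_chrom(refs$name, sex_chroms)]
  sex_present <- refs$name[is_sex_chrom(refs$name, sex_chroms)]
  # map each requested sex chromosome to the name present in the references
  sex_map <- vapply(sex_chroms, function(s) {
    hit <- sex_present[sub("^chr", "", sex_present) == sub("^chr", "", s)]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))

  rows <- lapply(profiles, function(p) {
    cns <- vapply(sex_map, function(ch) {
      if (is.na(ch)) return(0)
      estimate_copy_number(p, ch, masks[[ch]])
    }, numeric(1))
    sex <- infer_sex(cns[[1L]])
    av <- unlist(p$scaled[autosomal], use.names = FALSE)
    am <- unlist(masks[autosomal], use.names = FALSE)
    tp <- if (length(av)) tile_proportions(av, am)
          else list(p_low = 0, p_out = 0, p_in = 0, n_evaluated = 0L)
    out <- data.frame(sample_id = p$sample_id, stringsAsFactors = FALSE)
    for (i in seq_along(sex_chroms)) {
      out[[paste0("CN", sub("^chr", "", sex_chroms[i]))]] <- cns[[i]]
    }
    out$sex_label <- sex$sex_label
    out$ped_sex_code <- sex$ped_sex_code
    out$bins_in <- tp$p_in
    out$bins_out <- tp$p_out
    out$bins_low <- tp$p_low
    out$truncated <- isTRUE(p$flagged)
    out
  })
  qc <- do.call(rbind, rows)
  pcs <- matrix(0, nrow(qc), 5L)
  if (!is.null(pca) && ncol(pca$coords) > 0) {
    k <- min(5L, ncol(pca$coords))
    pcs[, seq_len(k)] <- pca$coords[, seq_len(k)]
  }
  colnames(pcs) <- paste0("PC", 1:5)
  cbind(qc, as.data.frame(pcs))
}
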