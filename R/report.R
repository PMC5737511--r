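#' Write the cohort coverage matrix as a BGZF-compressed BED file
#'
#' One row per 16384-bp tile over the non-excluded references (0-based
#' half-open coordinates, final tile truncated to the reference length),
#' one column of scaled coverage per sample, printed with three decimals.
#'
#' @param profiles List of `coverage_profile` objects on one tile grid.
#' @param refs Reference table.
#' @param path Output path (conventionally `<prefix>-indexcov.bed.gz`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(profiles, refs, path) {
  keep <- refs[!refs$excluded, , drop = FALSE]
  tiles <- tile_table(keep)
  dt <- data.table::data.table(
    chrom = tiles$chrom,
    start = format(tiles$start, scientific = FALSE, trim = TRUE),
    end = format(tiles$end, scientific = FALSE, trim = TRUE)
  )
  for (p in profiles) {
    v <- unlist(p$scaled[keep$name], use.names = FALSE)
    if (length(v) != nrow(tiles)) {
      stop("sample '", p$sample_id, "' does not match the tile grid")
    }
    dt[[p$sample_id]] <- sprintf("%.3f", v)
  }
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp), add = TRUE)
  header <- paste(c("#chrom", "start", "end",
                    vapply(profiles, `[[`, "", "sample_id")),
                  collapse = "\t")
  writeLines(header, tmp)
  data.table::fwrite(dt, tmp, sep = "\t", col.names = FALSE, quote = FALSE,
                     append = TRUE)
  ok <- tryCatch({
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    TRUE
  }, error = function(e) {
    stop("failed to write BED file '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Write the extended PED sample-QC table
#'
#' A standard 6-column pedigree prefix (family and sample identifiers, both
#' set to the sample name; unknown parents and phenotype coded -9; PED sex
#' codes 1 = male, 2 = female, 0 = unknown) extended with named columns for
#' the sex-chromosome copy numbers, the tile-proportion statistics and the
#' first five principal components.  Reals are printed with four decimals.
#'
#' @param qc Data.frame from [cohort_qc()].
#' @param sex_chroms Sex-chromosome names (column naming).
#' @param path Output path (conventionally `<prefix>-indexcov.ped`).
#' @return `path`, invisibly.
#' @export
write_ped <- function(qc, sex_chroms = c("X", "Y"), path) {
  cn_cols <- paste0("CN", sub("^chr", "", sex_chroms))
  header <- paste(c("#family_id", "sample_id", "paternal_id", "maternal_id",
                    "sex", "phenotype", cn_cols,
                    "bins.in", "bins.out", "bins.lo",
                    paste0("PC", 1:5)), collapse = "\t")
  num <- function(x) sprintf("%.4f", x)
  rows <- vapply(seq_len(nrow(qc)), function(i) {
    paste(c(qc$sample_id[i], qc$sample_id[i], "-9", "-9",
            qc$ped_sex_code[i], "-9",
            num(unlist(qc[i, cn_cols])),
            num(qc$bins_in[i]), num(qc$bins_out[i]), num(qc$bins_low[i]),
            num(unlist(qc[i, paste0("PC", 1:5)]))),
          collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

# ---- minimal deterministic SVG plotting -----------------------------------

.svg_header <- function(w, h) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                 'height="%d" viewBox="0 0 %d %d" ',
                 'font-family="sans-serif" font-size="11">'), w, h, w, h)
}

.svg_axes <- function(xlim, ylim, w, h, m, xlab, ylab, main) {
  sx <- function(x) m + (x - xlim[1]) / diff(xlim) * (w - 2 * m)
  sy <- function(y) h - m - (y - ylim[1]) / diff(ylim) * (h - 2 * m)
  xt <- pretty(xlim, 5); xt <- xt[xt >= xlim[1] & xt <= xlim[2]]
  yt <- pretty(ylim, 5); yt <- yt[yt >= ylim[1] & yt <= ylim[2]]
  c(
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="white" stroke="#888"/>',
            m, m, w - 2 * m, h - 2 * m),
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#ccc"/>',
            sx(xt), sy(ylim[1]), sx(xt), sy(ylim[2])),
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#ccc"/>',
            sx(xlim[1]), sy(yt), sx(xlim[2]), sy(yt)),
    sprintf('<text x="%.1f" y="%.1f" text-anchor="middle">%s</text>',
            sx(xt), h - m + 14, format(xt)),
    sprintf('<text x="%.1f" y="%.1f" text-anchor="end">%s</text>',
            m - 4, sy(yt) + 4, format(yt)),
    sprintf('<text x="%.1f" y="%.1f" text-anchor="middle" font-weight="bold">%s</text>',
            w / 2, m - 8, main),
    sprintf('<text x="%.1f" y="%.1f" text-anchor="middle">%s</text>',
            w / 2, h - 4, xlab),
    sprintf('<text x="12" y="%.1f" text-anchor="middle" transform="rotate(-90 12 %.1f)">%s</text>',
            h / 2, h / 2, ylab)
  )
}

.expand_lim <- function(v) {
  r <- range(v, finite = TRUE)
  if (!all(is.finite(r))) r <- c(0, 1)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  r + diff(r) * c(-0.05, 0.05)
}

# Scatter plot; each point carries a <title> so hovering identifies the
# sample in any browser.
.svg_scatter <- function(x, y, labels, xlab, ylab, main,
                         w = 440L, h = 360L) {
  m <- 45L
  xlim <- .expand_lim(x); ylim <- .expand_lim(y)
  sx <- function(v) m + (v - xlim[1]) / diff(xlim) * (w - 2 * m)
  sy <- function(v) h - m - (v - ylim[1]) / diff(ylim) * (h - 2 * m)
  pts <- sprintf(paste0('<circle cx="%.1f" cy="%.1f" r="4" fill="#3182bd" ',
                        'fill-opacity="0.7" stroke="#08519c"><title>%s</title></circle>'),
                 sx(x), sy(y), labels)
  c(.svg_header(w, h), .svg_axes(xlim, ylim, w, h, m, xlab, ylab, main),
    pts, "</svg>")
}

# One polyline per sample; hover identification again via <title>.
.svg_multiline <- function(x, ys, labels, xlab, ylab, main,
                           w = 760L, h = 300L, ylim = NULL) {
  m <- 45L
  xlim <- .expand_lim(x)
  if (is.null(ylim)) ylim <- .expand_lim(unlist(ys))
  sx <- function(v) m + (v - xlim[1]) / diff(xlim) * (w - 2 * m)
  sy <- function(v) h - m - (pmin(pmax(v, ylim[1]), ylim[2]) - ylim[1]) /
    diff(ylim) * (h - 2 * m)
  cols <- grDevices::hcl(seq(15, 375, length.out = length(ys) + 1L)[-1L],
                         100, 55)
  lines <- vapply(seq_along(ys), function(i) {
    pts <- paste(sprintf("%.1f,%.1f", sx(x), sy(ys[[i]])), collapse = " ")
    sprintf(paste0('<polyline points="%s" fill="none" stroke="%s" ',
                   'stroke-width="1.2" stroke-opacity="0.8">',
                   '<title>%s</title></polyline>'),
            pts, cols[i], labels[i])
  }, character(1))
  c(.svg_header(w, h), .svg_axes(xlim, ylim, w, h, m, xlab, ylab, main),
    lines, "</svg>")
}

.write_svg <- function(svg, path) {
  writeLines(svg, path)
  invisible(path)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the HTML QC report
#'
#' Writes `index.html` plus per-chromosome pages into `output_dir`.  The
#' overview page shows, in order: the sex plot (CN X vs CN Y), the tile
#' plot (proportion of low tiles vs proportion outside 0.85--1.15), two PCA
#' plots (PC1 vs PC2 and PC1 vs PC3), download links for the BED/PED
#' files, and per-chromosome thumbnails (coverage track and reverse CDF),
#' each linked to a per-chromosome page whose plots identify samples on
#' hover.  Every section links to a help description.  A failure while
#' drawing one chromosome degrades to a placeholder, never to a failed
#' report.
#'
#' @param profiles List of `coverage_profile` objects.
#' @param qc QC table from [cohort_qc()].
#' @param pca `pca_result` (or `NULL`).
#' @param cdfs Named list (per reference) of per-sample reverse-CDF tables
#'   from [coverage_cdf()], or `NULL` to compute on the fly.
#' @param refs Reference table.
#' @param output_dir Directory for the report files.
#' @param prefix File-name prefix used for the BED/PED links.
#' @param deterministic When `TRUE`, no timestamp is embedded so reruns are
#'   byte-identical.
#' @return Path to `index.html`, invisibly.
#' @export
render_html <- function(profiles, qc, pca, cdfs = NULL, refs, output_dir,
                        prefix = "cohort", deterministic = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- refs[!refs$excluded, , drop = FALSE]
  labels <- .html_escape(qc$sample_id)

  sex_svg <- .svg_scatter(qc[[grep("^CN", names(qc))[1L]]],
                          qc[[grep("^CN", names(qc))[2L]]],
                          labels, "inferred copy number: X",
                          "inferred copy number: Y", "Sex plot")
  tile_svg <- .svg_scatter(qc$bins_low, qc$bins_out, labels,
                           "proportion of tiles < 0.15",
                           "proportion of tiles outside [0.85, 1.15]",
                           "Tile plot")
  pca_svgs <- character(0)
  if (!is.null(pca) && ncol(pca$coords) >= 2L) {
    pca_svgs <- c(pca_svgs,
                  .svg_scatter(pca$coords[, 1L], pca$coords[, 2L], labels,
                               "PC1", "PC2", "PCA: PC1 vs PC2"))
    if (ncol(pca$coords) >= 3L) {
      pca_svgs <- c(pca_svgs,
                    .svg_scatter(pca$coords[, 1L], pca$coords[, 3L], labels,
                                 "PC1", "PC3", "PCA: PC1 vs PC3"))
    }
  }

  sample_ids <- vapply(profiles, `[[`, "", "sample_id")
  chrom_section <- character(0)
  placeholder <- '<svg xmlns="http://www.w3.org/2000/svg" width="300" height="120"><text x="10" y="60">plot unavailable</text></svg>'
  for (r in seq_len(nrow(keep))) {
    chrom <- keep$name[r]
    ok <- tryCatch({
      ys <- lapply(profiles, function(p) p$scaled[[chrom]])
      x_mb <- (seq_along(ys[[1L]]) - 0.5) * TILE_WIDTH / 1e6
      depth_svg <- .svg_multiline(x_mb, ys, labels,
                                  sprintf("position on %s (Mb)", chrom),
                                  "scaled coverage",
                                  sprintf("Coverage: %s", chrom),
                                  ylim = c(0, 2.5))
      cdf_list <- if (!is.null(cdfs) && !is.null(cdfs[[chrom]])) {
        cdfs[[chrom]]
      } else {
        lapply(ys, coverage_cdf)
      }
      cdf_svg <- .svg_multiline(cdf_list[[1L]]$threshold,
                                lapply(cdf_list, `[[`, "proportion"),
                                labels, "scaled coverage threshold",
                                "proportion of tiles >= threshold",
                                sprintf("Coverage CDF: %s", chrom),
                                ylim = c(0, 1.05))
      page <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                sprintf("<title>%s coverage</title></head><body>", chrom),
                sprintf("<h2>%s</h2>", chrom),
                "<p>Hover a line to identify the sample. <a href='index.html'>back to overview</a> | <a href='help.html#chrom'>what is this?</a></p>",
                depth_svg, cdf_svg, "</body></html>")
      writeLines(page, file.path(output_dir, sprintf("%s.html", chrom)))
      .write_svg(depth_svg, file.path(output_dir,
                                      sprintf("%s-depth-thumb.svg", chrom)))
      .write_svg(cdf_svg, file.path(output_dir,
                                    sprintf("%s-cdf-thumb.svg", chrom)))
      TRUE
    }, error = function(e) {
      warning("failed to plot ", chrom, ": ", conditionMessage(e))
      writeLines(placeholder, file.path(output_dir,
                                        sprintf("%s-depth-thumb.svg", chrom)))
      writeLines(placeholder, file.path(output_dir,
                                        sprintf("%s-cdf-thumb.svg", chrom)))
      writeLines(c("<!DOCTYPE html><html><body><p>plot unavailable</p></body></html>"),
                 file.path(output_dir, sprintf("%s.html", chrom)))
      FALSE
    })
    chrom_section <- c(chrom_section, sprintf(
      paste0('<div class="chrom"><h3>%s</h3>',
             '<a href="%s.html"><img src="%s-depth-thumb.svg" width="380" alt="%s coverage"/></a>',
             '<a href="%s.html"><img src="%s-cdf-thumb.svg" width="380" alt="%s CDF"/></a></div>'),
      chrom, chrom, chrom, chrom, chrom, chrom, chrom))
  }

  help <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>help</title></head><body>",
    "<h2 id='sex'>Sex plot</h2><p>Each point is a sample placed at its inferred X and Y copy number (twice the median scaled coverage of the chromosome). Males cluster at (1,1), females at (2,0); XXY/XYY aneuploidies form extra clusters and broken inputs (e.g. truncated indexes) fall near the origin.</p>",
    "<h2 id='tile'>Tile plot</h2><p>Proportion of usable autosomal 16384-bp tiles with scaled coverage below 0.15 (x) and outside [0.85, 1.15] (y). High x means missing data; high y means high coverage variance or bias.</p>",
    "<h2 id='pca'>PCA</h2><p>Samples projected onto the top principal components of the centered, byte-quantized scaled-coverage matrix. Separated clusters usually indicate sequencing or library-preparation batches.</p>",
    "<h2 id='downloads'>Downloads</h2><p>The BED file holds the scaled coverage of every sample at every tile; the PED file holds one QC row per sample (sex call, copy numbers, tile statistics, PC coordinates).</p>",
    "<h2 id='chrom'>Per-chromosome plots</h2><p>The coverage track shows scaled coverage along the chromosome, one line per sample; the reverse CDF shows the proportion of tiles covered at or above each threshold. Clean samples drop steeply through 1.0.</p>",
    "</body></html>")
  writeLines(help, file.path(output_dir, "help.html"))

  bed_name <- sprintf("%s-indexcov.bed.gz", prefix)
  ped_name <- sprintf("%s-indexcov.ped", prefix)
  idx <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>coverage QC overview</title>",
    "<style>body{font-family:sans-serif;margin:20px} .row{display:flex;flex-wrap:wrap;gap:16px} .chrom h3{margin:4px 0}</style>",
    "</head><body>",
    "<h1>Index-based coverage QC</h1>",
    sprintf("<p>%d samples, %d references.</p>", nrow(qc), nrow(keep)),
    "<h2>Sex plot <a href='help.html#sex'>?</a></h2>", sex_svg,
    "<h2>Tile plot <a href='help.html#tile'>?</a></h2>", tile_svg,
    "<h2>PCA <a href='help.html#pca'>?</a></h2>",
    if (length(pca_svgs)) c("<div class='row'>", pca_svgs, "</div>")
    else "<p>PCA requires at least two samples.</p>",
    "<h2>Downloads <a href='help.html#downloads'>?</a></h2>",
    sprintf("<ul><li><a href='%s'>scaled coverage BED</a></li><li><a href='%s'>sample QC PED</a></li></ul>",
            bed_name, ped_name),
    "<h2>Chromosomes <a href='help.html#chrom'>?</a></h2>",
    chrom_section,
    if (!deterministic) sprintf("<p><small>generated %s</small></p>",
                                format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "</body></html>")
  out <- file.path(output_dir, "index.html")
  writeLines(unlist(idx), out)
  invisible(out)
}
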