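# Report/visualization artifacts rendered from a DataTable: Manhattan
# plots, 2D heat and 3D checkerboard region snapshots, TRAX per-SNP
# documents, and a JSON region export. Images are styling; the
# machine-testable contract is the sidecar TSV/JSON written next to each
# image, whose numbers equal the DataTable cells exactly.

#' Region query
#'
#' Exactly one selector: an rs-number, a gene symbol (resolved against a
#' user-supplied BED file of gene spans), or explicit coordinates.
#'
#' @param snp_id rs-number (or any snp_id present in the table).
#' @param gene gene symbol; requires `genes_bed`.
#' @param chrom,start,end explicit coordinates (1-based inclusive).
#' @param flank_bp padding added on both sides (default 0).
#' @param genes_bed path to a BED file (chrom, start0, end, name).
#' @return list of class `RegionQuery`.
#' @export
region_query <- function(snp_id = NULL, gene = NULL, chrom = NULL,
                         start = NULL, end = NULL, flank_bp = 0,
                         genes_bed = NULL) {
  n_sel <- (!is.null(snp_id)) + (!is.null(gene)) + (!is.null(chrom))
  if (n_sel != 1)
    stop("exactly one of snp_id, gene or chrom/start/end must be given")
  if (!is.null(chrom)) {
    stopifnot(!is.null(start), !is.null(end))
    if (start >= end) stop("start must be < end")
  }
  if (!is.null(gene) && is.null(genes_bed))
    stop("gene queries require a genes_bed file")
  structure(list(snp_id = snp_id, gene = gene, chrom = chrom,
                 start = start, end = end, flank_bp = flank_bp,
                 genes_bed = genes_bed),
            class = "RegionQuery")
}

#' Parse a "chrN:start-end" region string
#'
#' Thousands separators in the coordinates are accepted and stripped.
#'
#' @param s region string, e.g. `"chr2:204,000,000-205,000,000"`.
#' @param flank_bp padding.
#' @return a [region_query()].
#' @export
parse_region <- function(s, flank_bp = 0) {
  m <- regmatches(s, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", s))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", s)
  num <- function(x) as.integer(gsub(",", "", x, fixed = TRUE))
  region_query(chrom = m[2], start = num(m[3]), end = num(m[4]),
               flank_bp = flank_bp)
}

# resolve a RegionQuery to variant indices of a DataTable
resolve_region <- function(table, region) {
  stopifnot(inherits(region, "RegionQuery"))
  v <- table$variants
  if (!is.null(region$snp_id)) {
    i <- match(region$snp_id, v$snp_id)
    if (is.na(i)) stop("region query: unknown SNP ", region$snp_id)
    sel <- which(v$chrom == v$chrom[i] &
                 abs(v$pos - v$pos[i]) <= region$flank_bp)
    if (!length(sel)) sel <- i
    return(sort(unique(c(sel, i))))
  }
  if (!is.null(region$gene)) {
    bed <- read.table(region$genes_bed, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    names(bed)[1:4] <- c("chrom", "start0", "end", "name")
    hit <- bed[bed$name == region$gene, , drop = FALSE]
    if (!nrow(hit)) stop("region query: gene not in BED: ", region$gene)
    sel <- which(v$chrom == hit$chrom[1] &
                 v$pos >= hit$start0[1] + 1 - region$flank_bp &
                 v$pos <= hit$end[1] + region$flank_bp)
  } else {
    sel <- which(v$chrom == region$chrom &
                 v$pos >= region$start - region$flank_bp &
                 v$pos <= region$end + region$flank_bp)
  }
  if (!length(sel))
    stop("region query selects no SNPs (",
         region$gene %||% paste0(region$chrom, ":", region$start, "-",
                                 region$end), ")")
  sel
}

#' Color scale for snapshot rendering
#'
#' p-values above the first bin edge (default 0.05) map to neutral light
#' grey; deeper bins map to richer colors. Hue encodes the QAS
#' direction: green for resistant (QAS < 1), red for susceptible
#' (QAS > 1); intensity grows with |log10 QAS| up to `qas_cap`.
#'
#' @param p_bins strictly decreasing p thresholds; values above
#'   `p_bins[1]` are neutral (bin 0).
#' @param qas_cap QAS magnitude at which intensity saturates.
#' @return list of class `ColorScale`.
#' @export
color_scale <- function(p_bins = c(0.05, 1e-2, 1e-3, 1e-4, 1e-5, 1e-8),
                        qas_cap = 10) {
  if (any(diff(p_bins) >= 0)) stop("p_bins must be strictly decreasing")
  structure(list(p_bins = p_bins, qas_cap = qas_cap),
            class = "ColorScale")
}

#' Map a (p, QAS) cell to bin, hue and intensity
#'
#' @param p,qas cell values (vectorized).
#' @param scale a [color_scale()].
#' @return data.frame: `bin` (0 = neutral), `hue` (`"green"`, `"red"`,
#'   `"neutral"`), `intensity` in \[0, 1\].
#' @export
cell_style <- function(p, qas, scale = color_scale()) {
  bin <- vapply(p, function(pp)
    if (is.na(pp)) NA_integer_ else sum(pp <= scale$p_bins), integer(1))
  hue <- ifelse(is.na(qas) | qas == 1, "neutral",
                ifelse(qas < 1, "green", "red"))
  intensity <- ifelse(is.na(qas), 0,
                      pmin(1, abs(log10(qas)) / log10(scale$qas_cap)))
  data.frame(bin = bin, hue = hue, intensity = intensity,
             stringsAsFactors = FALSE)
}

cell_color <- function(bin, hue, intensity, scale) {
  nb <- length(scale$p_bins)
  ifelse(is.na(bin), "#FFFFFF",
  ifelse(bin == 0, grey(0.92),
         ifelse(hue == "red", hsv(0, 0.25 + 0.75 * intensity, 1 - 0.3 * bin / nb),
         ifelse(hue == "green", hsv(1 / 3, 0.25 + 0.75 * intensity,
                                    1 - 0.3 * bin / nb),
                grey(0.75 - 0.4 * bin / nb)))))
}

#' Manhattan plot for one test
#'
#' -log10 p against position, chromosomes in alternating shades,
#' horizontal guides at the configured thresholds. Deterministic given
#' its inputs.
#'
#' @param table a `DataTable`.
#' @param test_id one test.
#' @param out_path output PNG path.
#' @param guides p-value guide lines (default 1e-5 and 5e-8).
#' @param width,height image size in pixels.
#' @return `out_path`, invisibly.
#' @export
manhattan <- function(table, test_id, out_path, guides = c(1e-5, 5e-8),
                      width = 1200, height = 400) {
  j <- match(test_id, table$tests$test_id)
  if (is.na(j)) stop("unknown test: ", test_id)
  v <- table$variants
  y <- neglog10(table$p[, j])
  chroms <- unique(v$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc)
    max(v$pos[v$chrom == cc]) + 1e6, numeric(1))))
  x <- v$pos + offs[match(v$chrom, chroms)]
  shade <- (match(v$chrom, chroms) %% 2 == 0)
  png(out_path, width = width, height = height)
  op <- par(mar = c(4, 4, 2, 1))
  ylim <- c(0, max(c(y, neglog10(guides)), na.rm = TRUE) * 1.05)
  plot(x, y, pch = 20, cex = 0.6, col = ifelse(shade, "grey40", "steelblue"),
       xlab = "position", ylab = "-log10 p", main = test_id, xaxt = "n",
       ylim = ylim)
  mids <- vapply(chroms, function(cc) mean(range(x[v$chrom == cc])),
                 numeric(1))
  axis(1, at = mids, labels = chroms)
  abline(h = neglog10(guides), lty = 2, col = "red")
  par(op)
  dev.off()
  invisible(out_path)
}

snapshot_cells <- function(table, region, tests, scale, polarized,
                           ptable = NULL) {
  sel <- resolve_region(table, region)
  jt <- if (is.null(tests)) seq_len(ncol(table$p)) else
    scope_tests(table, tests)
  sub <- table
  if (polarized) {
    if (is.null(ptable))
      stop("polarized snapshots need a PolarizationTable")
    sub <- polarize(sub, ptable)
  }
  grid <- expand.grid(si = sel, tj = jt, KEEP.OUT.ATTRS = FALSE)
  p <- sub$p[cbind(grid$si, grid$tj)]
  qas <- sub$qas[cbind(grid$si, grid$tj)]
  style <- cell_style(p, qas, scale)
  data.frame(snp_id = sub$variants$snp_id[grid$si],
             chrom = sub$variants$chrom[grid$si],
             pos = sub$variants$pos[grid$si],
             test_id = sub$tests$test_id[grid$tj],
             p = p, qas = qas, height = neglog10(p),
             bin = style$bin, hue = style$hue,
             intensity = style$intensity, stringsAsFactors = FALSE)
}

#' 2D heat snapshot of a region
#'
#' Grid of SNPs (rows, in coordinate order) by tests (columns), each
#' cell colored by its p-value bin. The exact bin index per cell goes to
#' the sidecar TSV `<out_path>.cells.tsv` — that file, not the pixels,
#' is the testable contract.
#'
#' @param table a `DataTable`.
#' @param region a [region_query()].
#' @param tests test scope (`NULL` = all; test_ids or a stage label).
#' @param scale a [color_scale()].
#' @param polarized invert QAS per `ptable` before styling.
#' @param ptable `PolarizationTable` (required when `polarized`).
#' @param out_path output PNG path.
#' @return the cell data.frame, invisibly.
#' @export
snapshot_2d <- function(table, region, tests = NULL,
                        scale = color_scale(), polarized = FALSE,
                        ptable = NULL, out_path) {
  cells <- snapshot_cells(table, region, tests, scale, polarized, ptable)
  write.table(cells, paste0(out_path, ".cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  snps <- unique(cells$snp_id)
  tids <- unique(cells$test_id)
  binm <- matrix(cells$bin, nrow = length(snps))
  png(out_path, width = max(400, 8 * length(tids) + 200),
      height = max(300, 6 * length(snps) + 150))
  op <- par(mar = c(6, 6, 2, 1))
  nb <- length(scale$p_bins)
  cols <- c("#FFFFFF", grey(0.92),
            vapply(seq_len(nb - 1) / (nb - 1), function(z)
              hsv(0.62, 0.3 + 0.7 * z, 1 - 0.35 * z), character(1)))
  image(x = seq_along(tids), y = seq_along(snps),
        z = t(ifelse(is.na(binm), -1, binm)),
        zlim = c(-1, nb), col = cols, xlab = "", ylab = "", axes = FALSE,
        main = "2D snapshot (p-value bins)")
  axis(1, at = seq_along(tids), labels = tids, las = 2, cex.axis = 0.5)
  axis(2, at = seq_along(snps), labels = snps, las = 1, cex.axis = 0.5)
  par(op)
  dev.off()
  invisible(cells)
}

#' 3D checkerboard snapshot of a region
#'
#' Block height is -log10 p; hue is green for QAS < 1, red for QAS > 1,
#' neutral at 1; intensity grows with |log10 QAS|. Rendered as a shaded
#' tile grid with per-cell height annotation; the sidecar TSV
#' `<out_path>.blocks.tsv` lists (snp, test, height, hue, intensity).
#'
#' @inheritParams snapshot_2d
#' @return the block data.frame, invisibly.
#' @export
snapshot_3d <- function(table, region, tests = NULL,
                        scale = color_scale(), polarized = FALSE,
                        ptable = NULL, out_path) {
  cells <- snapshot_cells(table, region, tests, scale, polarized, ptable)
  blocks <- cells[, c("snp_id", "chrom", "pos", "test_id", "p", "qas",
                      "height", "hue", "intensity")]
  write.table(blocks, paste0(out_path, ".blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  snps <- unique(cells$snp_id)
  tids <- unique(cells$test_id)
  png(out_path, width = max(400, 8 * length(tids) + 200),
      height = max(300, 6 * length(snps) + 150))
  op <- par(mar = c(6, 6, 2, 1))
  plot(NA, xlim = c(0.5, length(tids) + 0.5),
       ylim = c(0.5, length(snps) + 0.5), xlab = "", ylab = "",
       axes = FALSE, main = "3D snapshot (height = -log10 p, color = QAS)")
  hmax <- max(c(cells$height, 1), na.rm = TRUE)
  for (r in seq_len(nrow(cells))) {
    i <- match(cells$snp_id[r], snps)
    j <- match(cells$test_id[r], tids)
    h <- cells$height[r]
    if (is.na(h)) next
    sz <- 0.15 + 0.35 * min(1, h / hmax)
    rect(j - sz, i - sz, j + sz, i + sz,
         col = cell_color(cells$bin[r], cells$hue[r],
                          cells$intensity[r], scale), border = NA)
  }
  axis(1, at = seq_along(tids), labels = tids, las = 2, cex.axis = 0.5)
  axis(2, at = seq_along(snps), labels = snps, las = 1, cex.axis = 0.5)
  par(op)
  dev.off()
  invisible(blocks)
}

#' Export a region as versioned JSON
#'
#' Ordered SNP records with per-test (p, -log10 p, QAS, hue, height),
#' ready for any front-end.
#'
#' @inheritParams snapshot_2d
#' @param out_path output JSON path (`NULL` returns the list only).
#' @return the export list, invisibly when written.
#' @export
export_region_json <- function(table, region, tests = NULL,
                               scale = color_scale(), polarized = FALSE,
                               ptable = NULL, out_path = NULL) {
  cells <- snapshot_cells(table, region, tests, scale, polarized, ptable)
  snps <- unique(cells$snp_id)
  records <- lapply(snps, function(sid) {
    sub <- cells[cells$snp_id == sid, , drop = FALSE]
    list(snp_id = sid, chrom = sub$chrom[1], pos = sub$pos[1],
         tests = lapply(seq_len(nrow(sub)), function(r)
           list(test_id = sub$test_id[r], p = sub$p[r],
                neg_log10_p = sub$height[r], qas = sub$qas[r],
                hue = sub$hue[r], height = sub$height[r])))
  })
  out <- list(schema = "gwascan-region/1", polarized = polarized,
              n_snps = length(snps),
              n_tests = length(unique(cells$test_id)),
              snps = records)
  if (!is.null(out_path)) {
    jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(out))
  }
  out
}
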