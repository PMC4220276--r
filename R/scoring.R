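# Windowed density of small p-values and top-hit ranking.

#' Density specification
#'
#' @param window_mode `"snps"` (window counted in SNPs per side) or
#'   `"kbp"` (kilobases per side).
#' @param half_width window half-width (> 0), in SNPs or Kbp.
#' @param aggregate combine per-test window means by `"mean"` or `"max"`.
#' @param test_scope `NULL` for all tests, a character vector of
#'   test_ids, or a stage label (`"I"` to `"IV"`, `"QC"`) selecting all
#'   tests of one disease stage.
#' @return list of class `DensitySpec`.
#' @export
density_spec <- function(window_mode = c("snps", "kbp"), half_width = 10,
                         aggregate = c("mean", "max"), test_scope = NULL) {
  window_mode <- match.arg(window_mode)
  aggregate <- match.arg(aggregate)
  stopifnot(half_width > 0)
  structure(list(window_mode = window_mode, half_width = half_width,
                 aggregate = aggregate, test_scope = test_scope),
            class = "DensitySpec")
}

# p-values are clamped away from zero so -log10 stays finite
neglog10 <- function(p) -log10(pmax(p, 1e-300))

scope_tests <- function(table, test_scope) {
  if (is.null(test_scope)) return(seq_len(ncol(table$p)))
  if (length(test_scope) == 1 && test_scope %in% table$tests$stage)
    return(which(table$tests$stage == test_scope))
  j <- match(test_scope, table$tests$test_id)
  if (anyNA(j)) stop("unknown test(s) in scope: ",
                     paste(test_scope[is.na(j)], collapse = ", "))
  j
}

#' Windowed -log10 p density per SNP
#'
#' For each SNP and each in-scope test, the mean of `-log10 p` over the
#' window centred at the SNP (its own value included, missing cells
#' skipped, windows truncated at chromosome ends); the per-test means
#' are then aggregated across tests by mean or max.
#'
#' @param table a `DataTable`.
#' @param spec a [density_spec()].
#' @return numeric vector, one density score per SNP (`NA` when every
#'   in-scope cell in the window is missing).
#' @export
density_score <- function(table, spec = density_spec()) {
  stopifnot(inherits(table, "DataTable"), inherits(spec, "DensitySpec"))
  jt <- scope_tests(table, spec$test_scope)
  nl <- neglog10(table$p[, jt, drop = FALSE])
  S <- nrow(nl)
  out <- rep(NA_real_, S)
  chrom <- table$variants$chrom
  pos <- table$variants$pos
  for (s in seq_len(S)) {
    if (spec$window_mode == "snps") {
      same <- which(chrom == chrom[s])
      k <- match(s, same)
      win <- same[max(1, k - spec$half_width):
                  min(length(same), k + spec$half_width)]
    } else {
      win <- which(chrom == chrom[s] &
                   abs(pos - pos[s]) <= spec$half_width * 1000)
    }
    lane <- colMeans(nl[win, , drop = FALSE], na.rm = TRUE)
    lane <- lane[is.finite(lane)]  # lanes all-missing in the window drop out
    if (length(lane))
      out[s] <- if (spec$aggregate == "mean") mean(lane) else max(lane)
  }
  out
}

#' Rank top hits
#'
#' Ranks SNPs by one of three criteria: `"logp"` (largest -log10 p over
#' the in-scope tests), `"qas"` (largest |log QAS|, so protective and
#' risk effects rank symmetrically), or `"density"` (windowed
#' [density_score()]). Ties are broken by (chrom, pos).
#'
#' @param table a `DataTable`.
#' @param criterion `"logp"`, `"qas"` or `"density"`.
#' @param k number of hits to return (capped at the SNP count).
#' @param test_scope as in [density_spec()].
#' @param spec density specification (criterion `"density"` only).
#' @return data.frame: `rank`, `snp_id`, `chrom`, `pos`, `criterion`,
#'   `score`, `best_test`.
#' @export
top_hits <- function(table, criterion = c("logp", "qas", "density"),
                     k = 10, test_scope = NULL, spec = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(table, "DataTable"), k >= 1)
  S <- nrow(table$p)
  if (!S) return(data.frame(rank = integer(0), snp_id = character(0),
                            chrom = character(0), pos = integer(0),
                            criterion = character(0), score = numeric(0),
                            best_test = character(0)))
  jt <- scope_tests(table, test_scope)
  ids <- table$tests$test_id[jt]

  row_best <- function(m) {
    score <- apply(m, 1, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    best <- apply(m, 1, function(r)
      if (all(is.na(r))) NA_character_ else ids[which.max(r)])
    list(score = score, best = best)
  }
  if (criterion == "logp") {
    rb <- row_best(neglog10(table$p[, jt, drop = FALSE]))
  } else if (criterion == "qas") {
    rb <- row_best(abs(log(table$qas[, jt, drop = FALSE])))
  } else {
    if (is.null(spec)) spec <- density_spec(test_scope = test_scope)
    score <- density_score(table, spec)
    # contributing test: the lane with the largest window mean would need
    # the window recomputed; report the lane with the smallest own p
    rb <- row_best(neglog10(table$p[, jt, drop = FALSE]))
    rb$score <- score
  }
  ord <- order(-rb$score, table$variants$chrom, table$variants$pos,
               na.last = TRUE)
  ord <- ord[!is.na(rb$score[ord])]
  ord <- head(ord, k)
  data.frame(rank = seq_along(ord), snp_id = table$variants$snp_id[ord],
             chrom = table$variants$chrom[ord],
             pos = table$variants$pos[ord],
             criterion = criterion, score = rb$score[ord],
             best_test = rb$best[ord], stringsAsFactors = FALSE)
}

#' Export a density track as BedGraph
#'
#' @param table a `DataTable`.
#' @param spec a [density_spec()].
#' @param path output path (chrom, start-1, end, score).
#' @export
write_density_bedgraph <- function(table, spec, path) {
  d <- density_score(table, spec)
  df <- data.frame(chrom = table$variants$chrom,
                   start = table$variants$pos - 1L,
                   end = table$variants$pos, score = d)
  df <- df[!is.na(df$score), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
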