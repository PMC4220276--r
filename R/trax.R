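# TRAX documents: per-SNP reports of every test result.
#
# trax_page: header (SNP identity, alleles, frequencies, populations) +
# one row per test with p and QAS + a QAS bar plot.
# trax_report: the page plus, per categorical test, the backing
# contingency table (with bar plot), and per survival test Kaplan-Meier
# curves for all three genotypes.
#
# The HTML is for humans; the sidecar TSVs written next to it carry the
# exact numbers (full double precision) and are the testable surface.

fmt_full <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

trax_header <- function(gm, table, snp_id) {
  i <- match(snp_id, gm$variants$snp_id)
  if (is.na(i)) stop("unknown SNP: ", snp_id)
  v <- gm$variants[i, ]
  maf <- as.numeric(compute_maf(gm$codes[, i]))
  pops <- unique(table$tests$group_id)
  pops <- pops[!is.na(pops)]
  list(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
       allele_major = v$allele_major, allele_minor = v$allele_minor,
       maf = maf, n_samples = sum(!is.na(gm$codes[, i])),
       populations = if (length(pops)) paste(pops, collapse = ", ")
                     else "unspecified")
}

#' TRAX front page for one SNP
#'
#' @param gm a `GenotypeMatrix` containing the SNP.
#' @param cohort the `CohortTable` (reserved for population annotation).
#' @param table the `DataTable` holding the SNP's test results.
#' @param snp_id the SNP.
#' @param out_path output HTML path; sidecar `<out_path>.tests.tsv`
#'   carries the exact per-test numbers, and `<out_path>.qas.png` the
#'   QAS bar plot.
#' @return invisible data.frame of the per-test summary.
#' @export
trax_page <- function(gm, cohort, table, snp_id, out_path) {
  hd <- trax_header(gm, table, snp_id)
  s <- match(snp_id, table$variants$snp_id)
  if (is.na(s)) stop("SNP not in DataTable: ", snp_id)
  summ <- data.frame(test_id = table$tests$test_id,
                     family = table$tests$family,
                     stage = table$tests$stage,
                     p = table$p[s, ], qas = table$qas[s, ],
                     stringsAsFactors = FALSE, row.names = NULL)
  side <- summ
  side$p <- fmt_full(side$p); side$qas <- fmt_full(side$qas)
  write.table(side, paste0(out_path, ".tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  png(paste0(out_path, ".qas.png"), width = 900,
      height = max(300, 14 * nrow(summ)))
  op <- par(mar = c(4, 10, 2, 1))
  lq <- log(summ$qas)
  lq[is.na(lq)] <- 0
  barplot(rev(lq), horiz = TRUE, names.arg = rev(summ$test_id),
          las = 1, cex.names = 0.45,
          col = rev(ifelse(is.na(summ$qas) | summ$qas == 1, "grey",
                           ifelse(summ$qas > 1, "firebrick", "forestgreen"))),
          xlab = "log QAS (red susceptible, green resistant)")
  abline(v = 0)
  par(op)
  dev.off()

  rows <- paste0("<tr><td>", summ$test_id, "</td><td>", summ$family,
                 "</td><td>", summ$stage, "</td><td>", fmt_full(summ$p),
                 "</td><td>", fmt_full(summ$qas), "</td></tr>",
                 collapse = "\n")
  html <- paste0(
    "<html><head><title>TRAX ", hd$snp_id, "</title></head><body>",
    "<h1>TRAX PAGE: ", hd$snp_id, "</h1>",
    "<table border='1'>",
    "<tr><th>SNP</th><td>", hd$snp_id, "</td></tr>",
    "<tr><th>Coordinate</th><td>", hd$chrom, ":", hd$pos, "</td></tr>",
    "<tr><th>Alleles (major/minor)</th><td>", hd$allele_major, "/",
    hd$allele_minor, "</td></tr>",
    "<tr><th>MAF</th><td>", fmt_full(hd$maf), "</td></tr>",
    "<tr><th>Genotyped samples</th><td>", hd$n_samples, "</td></tr>",
    "<tr><th>Populations</th><td>", hd$populations, "</td></tr>",
    "</table>",
    "<h2>All tests (", nrow(summ), ")</h2>",
    "<img src='", basename(out_path), ".qas.png'/>",
    "<table border='1'><tr><th>test</th><th>family</th><th>stage</th>",
    "<th>p</th><th>QAS</th></tr>", rows, "</table>",
    "</body></html>")
  writeLines(html, out_path)
  invisible(summ)
}

# survival backing data for one descriptor at one SNP; NULL when the
# family is categorical
survival_backing <- function(des, cohort, codes) {
  fam <- des$family
  if (!fam %in% c("PHAZ", "SEQSA", "SEQS1", "HRTS")) return(NULL)
  if (fam == "PHAZ") {
    sel <- cohort$risk_group %in% "SC"
    tc <- paste0(des$endpoint, "_time"); ec <- paste0(des$endpoint, "_event")
    if (!all(c(tc, ec) %in% names(cohort))) return(NULL)
    list(time = cohort[[tc]][sel], event = cohort[[ec]][sel],
         codes = codes[sel])
  } else if (fam %in% c("SEQSA", "SEQS1")) {
    sel <- cohort$risk_group %in% "SC"
    tc <- paste0(des$endpoint, "_time"); ec <- paste0(des$endpoint, "_event")
    fc <- paste0(des$endpoint, "_first")
    if (!all(c(tc, ec) %in% names(cohort))) return(NULL)
    occurred <- !is.na(cohort[[ec]]) & cohort[[ec]] != 0
    ev <- if (fam == "SEQSA") as.integer(occurred)
          else if (fc %in% names(cohort))
            as.integer(occurred & !is.na(cohort[[fc]]) & cohort[[fc]] != 0)
          else return(NULL)
    ev[is.na(cohort[[ec]])] <- NA_integer_
    list(time = cohort[[tc]][sel], event = ev[sel], codes = codes[sel])
  } else {
    tc <- paste0("haart_", des$endpoint, "_time")
    ec <- paste0("haart_", des$endpoint, "_event")
    if (!all(c(tc, ec) %in% names(cohort))) return(NULL)
    sel <- !is.na(cohort[[tc]])
    list(time = cohort[[tc]][sel], event = cohort[[ec]][sel],
         codes = codes[sel])
  }
}

#' Kaplan-Meier estimates per genotype
#'
#' Product-limit curves of one survival outcome stratified by the three
#' genotype classes (0/1/2 minor alleles).
#'
#' @param time,event right-censored outcome.
#' @param codes dosage codes.
#' @return data.frame: `genotype`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_by_genotype <- function(time, event, codes) {
  ok <- !is.na(time) & !is.na(event) & !is.na(codes)
  if (!sum(ok)) return(NULL)
  time <- time[ok]; event <- event[ok]; g <- factor(codes[ok], 0:2)
  out <- list()
  for (lev in levels(g)) {
    m <- g == lev
    if (!sum(m)) next
    fit <- survfit(Surv(time[m], event[m]) ~ 1)
    out[[lev]] <- data.frame(genotype = as.integer(lev), time = fit$time,
                             n_risk = fit$n.risk, n_event = fit$n.event,
                             surv = fit$surv)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Full TRAX report for one SNP
#'
#' The TRAX page content plus the statistics behind every test: the
#' backing contingency table and bar plot for each categorical test, and
#' Kaplan-Meier survival curves for all three genotypes for each
#' survival test. Requires the raw genotype and clinical data; with a
#' summary-only DataTable use [trax_page()].
#'
#' @inheritParams trax_page
#' @return invisible list with `summary`, `contingency` (long data.frame)
#'   and `km` (long data.frame); sidecars `<out_path>.contingency.tsv`
#'   and `<out_path>.km.tsv` are written next to the HTML.
#' @export
trax_report <- function(gm, cohort, table, snp_id, out_path) {
  if (is.null(gm) || is.null(cohort)) {
    warning("genotype/clinical data unavailable; degrading to TRAX page")
    return(trax_page(gm, cohort, table, snp_id, out_path))
  }
  summ <- trax_page(gm, cohort, table, snp_id, out_path)
  s <- match(snp_id, gm$variants$snp_id)
  codes <- gm$codes[, s]
  idx <- match(gm$samples, cohort$sample_id)
  coh <- cohort[idx, , drop = FALSE]

  cont <- list(); km <- list()
  for (t in seq_len(nrow(table$tests))) {
    des <- table$tests[t, ]
    sb <- survival_backing(des, coh, codes)
    if (!is.null(sb)) {
      k <- km_by_genotype(sb$time, sb$event, sb$codes)
      if (!is.null(k)) {
        k$test_id <- des$test_id
        km[[length(km) + 1]] <- k
      }
    } else {
      sel <- subset_for_test(coh, des)
      runner <- test_runner(des, coh, sel)
      res <- tryCatch(runner(codes), error = function(e) NULL)
      if (!is.null(res) && !is.null(res$cells)) {
        tab <- as.data.frame(res$cells, stringsAsFactors = FALSE)
        names(tab) <- c("exposure", "outcome", "count")
        tab$test_id <- des$test_id
        cont[[length(cont) + 1]] <- tab
      }
    }
  }
  cont <- if (length(cont)) do.call(rbind, cont) else
    data.frame(exposure = character(0), outcome = character(0),
               count = integer(0), test_id = character(0))
  km <- if (length(km)) do.call(rbind, km) else
    data.frame(genotype = integer(0), time = numeric(0),
               n_risk = integer(0), n_event = integer(0),
               surv = numeric(0), test_id = character(0))
  kside <- km; kside$surv <- fmt_full(kside$surv)
  write.table(cont, paste0(out_path, ".contingency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(kside, paste0(out_path, ".km.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # append detail sections to the page HTML
  html <- readLines(out_path)
  detail <- c("<h2>Categorical tests: contingency tables</h2>",
              if (nrow(cont)) paste0(
                "<pre>", paste(utils::capture.output(print(cont)),
                               collapse = "\n"), "</pre>") else
                "<p>none</p>",
              "<h2>Survival tests: Kaplan-Meier by genotype</h2>",
              if (nrow(km)) paste0(
                "<pre>", paste(utils::capture.output(print(km)),
                               collapse = "\n"), "</pre>") else
                "<p>none</p>")
  html <- sub("</body></html>",
              paste(c(detail, "</body></html>"), collapse = "\n"),
              paste(html, collapse = "\n"), fixed = TRUE)
  writeLines(html, out_path)
  invisible(list(summary = summ, contingency = cont, km = km))
}
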