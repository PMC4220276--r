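# The Data Table: the SNP x test grid of (p, QAS) results that every
# downstream feature (polarization, density, snapshots, TRAX) consumes.

#' Construct a DataTable
#'
#' @param variants variant data.frame (as in a `GenotypeMatrix`).
#' @param tests test-descriptor data.frame (as from
#'   [enumerate_battery()]).
#' @param p,qas numeric matrices, variants x tests; `NA` = missing cell.
#' @param n_used optional integer matrix of per-cell sample counts.
#' @param reason optional character matrix of missing-cell reason codes.
#' @return object of class `DataTable`.
#' @export
data_table <- function(variants, tests, p, qas, n_used = NULL,
                       reason = NULL) {
  stopifnot(is.data.frame(variants), is.data.frame(tests),
            nrow(p) == nrow(variants), ncol(p) == nrow(tests),
            all(dim(p) == dim(qas)))
  bad_p <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad_p)) stop("p-values outside [0, 1]")
  bad_q <- !is.na(qas) & qas <= 0
  if (any(bad_q)) stop("QAS values must be positive")
  if (any(is.na(p) != is.na(qas) & is.na(p)))
    stop("cells with QAS but no p-value")
  dimnames(p) <- dimnames(qas) <- list(variants$snp_id, tests$test_id)
  structure(list(variants = variants, tests = tests, p = p, qas = qas,
                 n_used = n_used, reason = reason),
            class = "DataTable")
}

#' @export
print.DataTable <- function(x, ...) {
  cat(sprintf("DataTable: %d SNPs x %d tests (%d%% cells filled)\n",
              nrow(x$p), ncol(x$p),
              round(100 * mean(!is.na(x$p)))))
  invisible(x)
}

#' @export
dim.DataTable <- function(x) dim(x$p)

#' Run a test battery over a genotype matrix and cohort
#'
#' Executes every enumerated test of the battery at every SNP, producing
#' the Data Table. Missing genotype codes are dropped per test (pairwise
#' deletion); failures are recorded per cell as reason codes, never
#' fatal. Deterministic given its inputs.
#'
#' @param gm a `GenotypeMatrix` (QC'd).
#' @param cohort a `CohortTable` whose rows will be matched to
#'   `gm$samples` by `sample_id`.
#' @param config a `BatteryConfig` or an already-enumerated descriptor
#'   data.frame.
#' @param verbose log progress per chromosome (default `FALSE`).
#' @return a `DataTable`.
#' @export
run_battery <- function(gm, cohort, config, verbose = FALSE) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  tests <- if (inherits(config, "BatteryConfig"))
    enumerate_battery(config) else config
  idx <- match(gm$samples, cohort$sample_id)
  cohort <- cohort[idx, , drop = FALSE]  # rows with NA index become all-NA

  S <- nrow(gm$variants); T <- nrow(tests)
  p <- matrix(NA_real_, S, T)
  qas <- matrix(NA_real_, S, T)
  n_used <- matrix(0L, S, T)
  reason <- matrix(NA_character_, S, T)

  chroms <- gm$variants$chrom
  for (t in seq_len(T)) {
    des <- tests[t, ]
    sel <- subset_for_test(cohort, des)
    runner <- test_runner(des, cohort, sel)
    for (s in seq_len(S)) {
      res <- tryCatch(runner(gm$codes[, s]),
                      error = function(e) assoc_missing(conditionMessage(e)))
      p[s, t] <- res$p_value
      qas[s, t] <- res$qas
      n_used[s, t] <- res$n_used
      reason[s, t] <- res$reason
    }
    if (verbose)
      message(sprintf("[battery] %s done (%d/%d)", des$test_id, t, T))
  }
  data_table(gm$variants, tests, p, qas, n_used, reason)
}

# sample inclusion mask for a descriptor's cohort subset
subset_for_test <- function(cohort, des) {
  sel <- rep(TRUE, nrow(cohort))
  sub <- des$subset
  if (!is.na(sub) && sub != "pooled" && "cohort" %in% names(cohort)) {
    hit <- !is.na(cohort$cohort) & cohort$cohort == sub
    if (any(hit)) sel <- hit  # unmatched labels fall back to all samples
  }
  sel & !is.na(cohort$sample_id)
}

# returns function(codes) -> AssociationResult for one descriptor
test_runner <- function(des, cohort, sel) {
  family <- des$family
  model <- des$model
  bp <- if (!is.na(des$breakpoints))
    as.numeric(strsplit(des$breakpoints, ",")[[1]]) else NULL
  mask <- function(codes) {
    codes[!sel] <- NA_integer_
    codes
  }
  switch(family,
    INF = function(codes)
      infection_test(mask(codes), cohort$risk_group, des$contrast, model),
    PDCA2 = ,
    PDCAM = {
      tc <- paste0(des$endpoint, "_time"); ec <- paste0(des$endpoint, "_event")
      if (!all(c(tc, ec) %in% names(cohort)))
        return(function(codes) assoc_missing("endpoint_not_recorded"))
      prog <- cohort$risk_group %in% c("SC", "SP")
      classes <- ctsd_classify(cohort[[tc]], cohort[[ec]],
                               cohort$risk_group, bp)
      classes[!prog] <- NA_integer_
      function(codes) pdca_test(mask(codes), classes, model)
    },
    PHAZ = {
      tc <- paste0(des$endpoint, "_time"); ec <- paste0(des$endpoint, "_event")
      if (!all(c(tc, ec) %in% names(cohort)))
        return(function(codes) assoc_missing("endpoint_not_recorded"))
      sc <- cohort$risk_group %in% "SC"
      function(codes) {
        codes <- mask(codes)
        phaz_test(codes[sc], cohort[[tc]][sc], cohort[[ec]][sc], model)
      }
    },
    SEQSA = function(codes)
      sequelae_tests(mask(codes), cohort, des$endpoint, "any", "survival", model),
    SEQCA = function(codes)
      sequelae_tests(mask(codes), cohort, des$endpoint, "any", "categorical", model),
    SEQS1 = function(codes)
      sequelae_tests(mask(codes), cohort, des$endpoint, "first", "survival", model),
    SEQC1 = function(codes)
      sequelae_tests(mask(codes), cohort, des$endpoint, "first", "categorical", model),
    HRTS = function(codes)
      haart_tests(mask(codes), cohort, des$endpoint, "survival", model),
    HRTC = function(codes)
      haart_tests(mask(codes), cohort, des$endpoint, "categorical", model),
    HWE = function(codes) {
      g <- mask(codes)
      g <- g[!is.na(g)]
      if (!length(g)) return(assoc_missing("all_missing"))
      nAA <- sum(g == 0); nAa <- sum(g == 1); naa <- sum(g == 2)
      pv <- hwe_test(nAA, nAa, naa)
      # QAS: observed / expected heterozygosity (>1 = het excess)
      f <- (2 * naa + nAa) / (2 * length(g))
      exp_het <- 2 * f * (1 - f) * length(g)
      qas <- if (exp_het > 0) (nAa + 0.5) / (exp_het + 0.5) else 1
      assoc_result(as.numeric(pv), qas, "ez2", length(g))
    },
    stop("unknown family: ", family))
}

# --- TSV round-trip ------------------------------------------------------

#' Write a DataTable as TSV (plus a JSON test-descriptor sidecar)
#'
#' Columns: `SNP`, `CHR`, `POS`, `MAF`, then `<test_id>.P` and
#' `<test_id>.QAS` per test; missing cells are written as `NA`. Values
#' are printed to 6 significant digits, which the reader reproduces
#' losslessly. A sidecar `<path>.tests.json` carries the test
#' descriptors.
#'
#' @param table a `DataTable`.
#' @param path output TSV path.
#' @export
write_data_table <- function(table, path) {
  stopifnot(inherits(table, "DataTable"))
  S <- nrow(table$p)
  fmt <- function(m) apply(m, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.6g", col)))
  pm <- fmt(table$p); qm <- fmt(table$qas)
  if (S == 1) { pm <- matrix(pm, nrow = 1); qm <- matrix(qm, nrow = 1) }
  out <- data.frame(SNP = table$variants$snp_id,
                    CHR = table$variants$chrom,
                    POS = table$variants$pos,
                    MAF = sprintf("%.6g", table$variants$maf),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (t in seq_len(ncol(table$p))) {
    out[[paste0(table$tests$test_id[t], ".P")]] <- pm[, t]
    out[[paste0(table$tests$test_id[t], ".QAS")]] <- qm[, t]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table$tests, paste0(path, ".tests.json"),
                       dataframe = "rows", na = "null", auto_unbox = FALSE)
  invisible(path)
}

#' Read a DataTable written by [write_data_table()]
#'
#' @param path TSV path; expects the `<path>.tests.json` sidecar next to
#'   it (reconstructed minimally from the header if absent).
#' @return a `DataTable`.
#' @export
read_data_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  fixed <- c("SNP", "CHR", "POS", "MAF")
  if (!all(fixed %in% names(df)))
    stop("not a Data Table TSV: missing ",
         paste(setdiff(fixed, names(df)), collapse = ", "))
  rest <- setdiff(names(df), fixed)
  pcols <- grep("\\.P$", rest, value = TRUE)
  qcols <- grep("\\.QAS$", rest, value = TRUE)
  ids_p <- sub("\\.P$", "", pcols)
  ids_q <- sub("\\.QAS$", "", qcols)
  if (!identical(ids_p, ids_q))
    stop("header mismatch: every test needs a .P and a .QAS column in order")

  side <- paste0(path, ".tests.json")
  tests <- if (file.exists(side)) {
    tj <- jsonlite::read_json(side, simplifyVector = TRUE)
    as.data.frame(tj, stringsAsFactors = FALSE)
  } else {
    data.frame(test_id = ids_p, family = sub("_.*$", "", ids_p),
               stage = NA_character_, model = NA_character_,
               endpoint = NA_character_, contrast = NA_character_,
               breakpoints = NA_character_, subset = NA_character_,
               group_id = NA_character_, stringsAsFactors = FALSE)
  }
  if (!identical(tests$test_id, ids_p))
    stop("test-descriptor sidecar does not match TSV header")

  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  p <- sapply(df[pcols], num)
  qas <- sapply(df[qcols], num)
  if (nrow(df) == 1) {
    p <- matrix(p, nrow = 1); qas <- matrix(qas, nrow = 1)
  }
  variants <- data.frame(snp_id = df$SNP, chrom = df$CHR,
                         pos = as.integer(df$POS),
                         allele_major = NA_character_,
                         allele_minor = NA_character_,
                         maf = num(df$MAF), stringsAsFactors = FALSE)
  data_table(variants, tests, p, qas)
}
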