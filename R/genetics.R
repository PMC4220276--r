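# Genetic models, MAF, Hardy-Weinberg QC and genotype/sample filtering.

#' Minor allele frequency from dosage codes
#'
#' @param codes vector of {0, 1, 2, NA} minor-allele counts.
#' @return `min(f, 1 - f)` where `f` is the frequency of the counted
#'   allele among non-missing samples. The attribute `relabel` is `TRUE`
#'   when `f > 0.5`, i.e. the counted allele is really the major one.
#' @export
compute_maf <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("all genotypes missing; MAF undefined")
  f <- sum(codes) / (2 * length(codes))
  structure(min(f, 1 - f), relabel = f > 0.5)
}

#' Recode genotypes under a genetic model
#'
#' @param codes vector of {0, 1, 2, NA} minor-allele counts.
#' @param model `"D"` dominant (minor-allele carrier vs non-carrier),
#'   `"R"` recessive (homozygous minor vs rest), `"CD"` codominant (three
#'   ordered genotype classes), `"A"` allelic (each sample contributes two
#'   allele observations).
#' @return For D/R: 0/1 vector. For CD: the codes unchanged as ordered
#'   classes 0/1/2. For A: a vector of `2 * length(codes)` allele
#'   indicators (1 = minor). Missing codes propagate.
#' @export
code_genotypes <- function(codes, model) {
  if (!model %in% GENETIC_MODELS)
    stop("unknown genetic model: ", model)
  switch(model,
    D = ifelse(is.na(codes), NA_integer_, as.integer(codes >= 1)),
    R = ifelse(is.na(codes), NA_integer_, as.integer(codes == 2)),
    CD = as.integer(codes),
    A = {
      first <- ifelse(is.na(codes), NA_integer_, as.integer(codes >= 1))
      second <- ifelse(is.na(codes), NA_integer_, as.integer(codes == 2))
      as.integer(rbind(first, second))
    })
}

#' Hardy-Weinberg equilibrium test
#'
#' Exact conditional test (enumerating heterozygote counts given the
#' allele counts) for totals below `exact_limit`, chi-square with one
#' degree of freedom above it. Monomorphic sites return p = 1 with a
#' `monomorphic` attribute, by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @param exact_limit sample-size cutover between the exact and the
#'   chi-square computation (default 1000).
#' @param midp use the mid-p variant of the exact test (default `TRUE`;
#'   the plain exact test is conservative at typical GWAS sample sizes).
#' @return p-value in \[0, 1\].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, exact_limit = 1000, midp = TRUE) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  n_minor <- 2 * n_aa + n_Aa
  if (n_minor == 0 || n_minor == 2 * n)
    return(structure(1, monomorphic = TRUE))
  if (n < exact_limit) {
    hwe_exact(n_AA, n_Aa, n_aa, midp = midp)
  } else {
    p <- n_minor / (2 * n)
    expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

# Exact conditional HWE p-value: the distribution of the heterozygote
# count given the allele counts. Probabilities are summed over outcomes
# no more likely than the observed one (mid-p: half-weight on the
# observed outcome).
hwe_exact <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  n <- n_AA + n_Aa + n_aa
  n_min <- 2 * n_aa + n_Aa           # minor allele count
  n_maj <- 2 * n - n_min
  hets <- seq(n_min %% 2, min(n_min, n_maj), by = 2)
  # log P(het = h | allele counts), up to a constant
  logp <- vapply(hets, function(h) {
    hom_min <- (n_min - h) / 2
    hom_maj <- (n_maj - h) / 2
    h * log(2) - lfactorial(hom_maj) - lfactorial(h) - lfactorial(hom_min)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_Aa)
  sel <- prob <= prob[obs] + 1e-12
  p <- sum(prob[sel])
  if (midp) p <- p - prob[obs] / 2
  min(1, max(p, 0))
}

#' QC thresholds
#'
#' @param min_call_rate_snp minimum per-SNP call rate (default 0.95).
#' @param min_call_rate_sample minimum per-sample call rate (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param min_hwe_p minimum Hardy-Weinberg p-value (default 1e-6).
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_call_rate_snp = 0.95,
                          min_call_rate_sample = 0.90,
                          min_maf = 0.01, min_hwe_p = 1e-6) {
  th <- list(min_call_rate_snp = min_call_rate_snp,
             min_call_rate_sample = min_call_rate_sample,
             min_maf = min_maf, min_hwe_p = min_hwe_p)
  stopifnot(all(unlist(th) >= 0), all(unlist(th) <= 1))
  structure(th, class = "QCThresholds")
}

#' Apply QC filters to a genotype matrix
#'
#' Filters are applied in a fixed order: sample call rate, then SNP call
#' rate, then MAF, then Hardy-Weinberg equilibrium, each on the data
#' surviving the previous step.
#'
#' @param gm a `GenotypeMatrix`.
#' @param thresholds a [qc_thresholds()] object.
#' @return The filtered `GenotypeMatrix`, with attributes `qc_counts`
#'   (named exclusion counts per criterion) and `qc_report` (data.frame:
#'   id, criterion, value, threshold, action).
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  th <- thresholds
  report <- list()
  note <- function(id, criterion, value) {
    report[[length(report) + 1]] <<- data.frame(
      id = id, criterion = criterion, value = value,
      threshold = switch(criterion,
                         sample_call_rate = th$min_call_rate_sample,
                         snp_call_rate = th$min_call_rate_snp,
                         maf = th$min_maf, hwe = th$min_hwe_p),
      action = "removed", stringsAsFactors = FALSE)
  }

  # 1. sample call rate
  cr_sample <- rowMeans(!is.na(gm$codes))
  drop_s <- cr_sample < th$min_call_rate_sample
  for (i in which(drop_s)) note(gm$samples[i], "sample_call_rate", cr_sample[i])
  if (any(drop_s)) gm <- subset_genotypes(gm, samples = !drop_s)

  # 2. SNP call rate
  cr_snp <- colMeans(!is.na(gm$codes))
  drop_cr <- cr_snp < th$min_call_rate_snp
  for (j in which(drop_cr)) note(gm$variants$snp_id[j], "snp_call_rate", cr_snp[j])

  # 3. MAF (on SNPs surviving call rate)
  maf <- gm$variants$maf
  drop_maf <- !drop_cr & (is.na(maf) | maf < th$min_maf)
  for (j in which(drop_maf)) note(gm$variants$snp_id[j], "maf", maf[j])

  # 4. HWE
  drop_hwe <- rep(FALSE, ncol(gm$codes))
  for (j in which(!drop_cr & !drop_maf)) {
    g <- gm$codes[, j]
    hp <- hwe_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
    if (hp < th$min_hwe_p) {
      drop_hwe[j] <- TRUE
      note(gm$variants$snp_id[j], "hwe", hp)
    }
  }

  keep <- !(drop_cr | drop_maf | drop_hwe)
  out <- if (all(keep)) gm else subset_genotypes(gm, snps = keep)
  counts <- c(sample_call_rate = sum(drop_s), snp_call_rate = sum(drop_cr),
              maf = sum(drop_maf), hwe = sum(drop_hwe))
  attr(out, "qc_counts") <- counts
  attr(out, "qc_report") <- if (length(report)) do.call(rbind, report) else
    data.frame(id = character(0), criterion = character(0),
               value = numeric(0), threshold = numeric(0),
               action = character(0))
  out
}

#' Write a QC exclusion report as TSV
#'
#' @param gm a QC'd `GenotypeMatrix` (output of [apply_qc()]).
#' @param path output path.
#' @export
write_qc_report <- function(gm, path) {
  rep <- attr(gm, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; run apply_qc() first")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
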