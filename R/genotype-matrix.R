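# GenotypeMatrix: samples x variants minor-allele dosage codes.
#
# `variants` is a data.frame with one row per SNP (snp_id, chrom, pos,
# allele_major, allele_minor, maf), strictly ordered by (chrom, pos);
# `codes` is an integer matrix (samples x variants) in {0, 1, 2, NA}
# counting copies of the minor allele.

#' Construct a genotype matrix anchored to the minor allele
#'
#' Builds the central genotype container. Columns whose stated allele "1"
#' turns out to be the major allele (frequency > 0.5) are flipped
#' (`code <- 2 - code`, alleles swapped) so that every column counts minor
#' alleles and every recomputed MAF is at most 0.5.
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_major`, `allele_minor`. A `maf` column, if absent, is
#'   recomputed from `codes`.
#' @param samples character vector of sample identifiers.
#' @param codes integer matrix, `length(samples)` rows by `nrow(variants)`
#'   columns, values in `{0, 1, 2, NA}` counting the `allele_minor` allele.
#' @param anchor_minor flip columns with allele frequency > 0.5 so codes
#'   always count the minor allele (default `TRUE`).
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(variants, samples, codes, anchor_minor = TRUE) {
  stopifnot(is.data.frame(variants), is.matrix(codes))
  req <- c("snp_id", "chrom", "pos", "allele_major", "allele_minor")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variants is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(codes))
    stop("ncol(codes) must equal nrow(variants)")
  if (length(samples) != nrow(codes))
    stop("nrow(codes) must equal length(samples)")
  if (anyDuplicated(variants$snp_id))
    stop("duplicate snp_id: ",
         variants$snp_id[anyDuplicated(variants$snp_id)])
  bad <- !(codes %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("genotype codes must be 0, 1, 2 or NA")
  storage.mode(codes) <- "integer"

  # strict (chrom, pos) order, ties forbidden (window semantics downstream
  # assume a strict SNP order)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  codes <- codes[, o, drop = FALSE]
  dup <- duplicated(variants[, c("chrom", "pos")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate coordinate %s:%d (snp %s)",
                 variants$chrom[i], variants$pos[i], variants$snp_id[i]))
  }
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$allele_major == variants$allele_minor))
    stop("allele_major must differ from allele_minor")

  if (anchor_minor) {
    freq <- colMeans(codes, na.rm = TRUE) / 2
    flip <- which(!is.na(freq) & freq > 0.5)
    if (length(flip)) {
      codes[, flip] <- 2L - codes[, flip]
      tmp <- variants$allele_major[flip]
      variants$allele_major[flip] <- variants$allele_minor[flip]
      variants$allele_minor[flip] <- tmp
    }
  }
  variants$maf <- apply(codes, 2, function(g)
    if (all(is.na(g))) NA_real_ else compute_maf(g))
  rownames(variants) <- NULL
  dimnames(codes) <- list(samples, variants$snp_id)

  structure(list(variants = variants, samples = samples, codes = codes),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (%s)\n",
              length(x$samples), nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by variant and/or sample
#'
#' @param gm a `GenotypeMatrix`.
#' @param snps variant selector: indices, logical mask, or snp_ids.
#' @param samples sample selector: indices, logical mask, or ids.
#' @return A `GenotypeMatrix` (minor-allele anchoring re-applied, MAF
#'   recomputed on the retained samples).
#' @export
subset_genotypes <- function(gm, snps = NULL, samples = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  si <- resolve_index(snps, gm$variants$snp_id)
  pi <- resolve_index(samples, gm$samples)
  genotype_matrix(gm$variants[si, , drop = FALSE], gm$samples[pi],
                  gm$codes[pi, si, drop = FALSE])
}

resolve_index <- function(sel, ids) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) return(which(sel))
  if (is.character(sel)) {
    i <- match(sel, ids)
    if (anyNA(i)) stop("unknown id(s): ",
                       paste(sel[is.na(i)], collapse = ", "))
    return(i)
  }
  sel
}
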