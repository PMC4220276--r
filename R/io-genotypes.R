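# Genotype readers: plain TSV dosage tables and VCF 4.x (diploid GT).

#' Read genotypes from TSV or VCF
#'
#' Both formats are reduced to the same container: biallelic SNPs only,
#' codes counting minor alleles. Sites where the stated ALT (or "minor")
#' allele is in fact the major allele are recoded so that MAF <= 0.5 at
#' every SNP. Multi-allelic and non-SNP (indel) records are skipped and
#' counted in `attr(, "skipped")`.
#'
#' @param path path to the input file.
#' @param format `"tsv"` (columns: snp_id, chrom, pos, major, minor, then
#'   one 0/1/2/NA column per sample) or `"vcf"` (diploid GT field).
#' @return A [genotype_matrix()] with attribute `skipped` giving the
#'   number of records dropped.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  req <- c("snp_id", "chrom", "pos", "major", "minor")
  if (!all(req %in% names(df)))
    stop("TSV genotype file must have columns: ",
         paste(req, collapse = ", "), ", then one column per sample")
  sample_cols <- setdiff(names(df), req)
  if (!length(sample_cols)) stop("no sample columns found")
  variants <- data.frame(snp_id = df$snp_id, chrom = df$chrom,
                         pos = as.integer(df$pos),
                         allele_major = df$major, allele_minor = df$minor,
                         stringsAsFactors = FALSE)
  check_sorted(variants, path)
  keep <- nchar(variants$allele_major) == 1 & nchar(variants$allele_minor) == 1
  # samples x variants integer matrix
  codes <- vapply(df[sample_cols], function(col)
    suppressWarnings(as.integer(col)), integer(nrow(df)))
  if (nrow(df) == 1) codes <- matrix(codes, nrow = 1,
                                     dimnames = list(NULL, sample_cols))
  gm <- genotype_matrix(variants[keep, , drop = FALSE], sample_cols,
                        t(codes)[, keep, drop = FALSE])
  attr(gm, "skipped") <- sum(!keep)
  gm
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))

  # biallelic SNPs only
  is_snp <- nchar(fix[, "REF"]) == 1 & !is.na(fix[, "ALT"]) &
    nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  skipped <- sum(!is_snp)
  if (!any(is_snp)) stop("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "." | !nzchar(ids)
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  variants <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         allele_major = fix[, "REF"],
                         allele_minor = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  check_sorted(variants, path)

  # count ALT alleles in diploid GT calls; any missing allele -> NA
  codes <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  gm <- genotype_matrix(variants, colnames(gt), t(codes))
  attr(gm, "skipped") <- skipped
  gm
}

check_sorted <- function(variants, path) {
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants)))) {
    i <- which(o != seq_len(nrow(variants)))[1]
    stop(sprintf("%s: records not sorted by (chrom, pos); first offender %s at %s:%d",
                 path, variants$snp_id[i], variants$chrom[i], variants$pos[i]))
  }
  dup <- duplicated(variants[, c("chrom", "pos")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("%s: duplicate coordinate %s:%d", path,
                 variants$chrom[i], variants$pos[i]))
  }
  invisible(TRUE)
}

#' Write a genotype matrix as the plain TSV dosage format
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  df <- data.frame(snp_id = gm$variants$snp_id, chrom = gm$variants$chrom,
                   pos = gm$variants$pos, major = gm$variants$allele_major,
                   minor = gm$variants$allele_minor,
                   stringsAsFactors = FALSE)
  geno <- as.data.frame(t(gm$codes))
  names(geno) <- gm$samples
  write.table(cbind(df, geno), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
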