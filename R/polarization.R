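# LD polarization: signed D' between an index SNP and its neighbours,
# polarization marks, and QAS inversion for mark -1 rows.
#
# Minor alleles at any two loci can sit on the same haplotype background
# (coupling, D' > 0) or on opposite ones (repulsion, D' < 0). When a
# region's signal derives from one causal allele, proxies in repulsion
# show the opposite QAS direction purely as a labelling artifact;
# polarization inverts them so the region shows one direction.

#' Signed D' between two SNPs from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM over the ambiguous
#' double heterozygotes, then `D = p11 - pA * pB` is normalized by the
#' standard maximum for its sign. The sign is anchored to the minor
#' alleles at both loci.
#'
#' @param a,b minor-allele dosage codes at the two SNPs (same samples).
#' @param max_iter,tol EM iteration cap and convergence tolerance.
#' @return D' in \[-1, 1\], with attributes `D` (raw coefficient) and
#'   `em_converged`; `NA` when either locus is monomorphic among jointly
#'   non-missing samples.
#' @export
dprime <- function(a, b, max_iter = 200, tol = 1e-8) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  N <- length(a)
  if (!N) return(NA_real_)
  pA <- sum(a) / (2 * N); pB <- sum(b) / (2 * N)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)

  n <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) n[i + 1, j + 1] <- sum(a == i & b == j)
  # unambiguous haplotype counts (minor allele = 1)
  x11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  x10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  x01 <- 2 * n[1, 3] + n[2, 3] + n[1, 2]
  x00 <- 2 * n[1, 1] + n[2, 1] + n[1, 2]
  nd <- n[2, 2]  # double heterozygotes: phase unknown

  # canonical locus order so dprime(a, b) == dprime(b, a) to the bit:
  # D and D' are symmetric quantities, but floating-point summation
  # order is not
  if (pA > pB || (pA == pB && x10 > x01)) {
    tmp <- pA; pA <- pB; pB <- tmp
    tmp <- x10; x10 <- x01; x01 <- tmp
  }

  # observed-data log-likelihood of the genotype table given p11
  loglik <- function(p11) {
    hap <- c(p11, pA - p11, pB - p11, 1 - pA - pB + p11)  # 11,10,01,00
    if (min(hap) < -1e-12) return(-Inf)
    hap <- pmax(hap, 0)
    x11 * log(max(hap[1], 1e-300)) + x10 * log(max(hap[2], 1e-300)) +
      x01 * log(max(hap[3], 1e-300)) + x00 * log(max(hap[4], 1e-300)) +
      nd * log(max(2 * (hap[1] * hap[4] + hap[2] * hap[3]), 1e-300))
  }
  lo_p11 <- max(0, pA + pB - 1)
  hi_p11 <- min(pA, pB)
  run_em <- function(p11_0) {
    p11 <- p11_0; p10 <- pA - p11
    p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      denom <- p11 * p00 + p10 * p01
      pi_cis <- if (denom > 0) p11 * p00 / denom else 0.5
      c11 <- x11 + nd * pi_cis; c00 <- x00 + nd * pi_cis
      c10 <- x10 + nd * (1 - pi_cis); c01 <- x01 + nd * (1 - pi_cis)
      new <- c(c11, c10, c01, c00) / (2 * N)
      delta <- max(abs(new - c(p11, p10, p01, p00)))
      p11 <- new[1]; p10 <- new[2]; p01 <- new[3]; p00 <- new[4]
      if (delta < tol) { converged <- TRUE; break }
    }
    list(p11 = p11, converged = converged)
  }
  # the likelihood in p11 can be bimodal (coupling vs repulsion phase of
  # the double heterozygotes); run EM from the equilibrium point and
  # from near both feasibility boundaries, keep the best
  span <- hi_p11 - lo_p11
  starts <- unique(c(pA * pB, lo_p11 + 0.02 * span, hi_p11 - 0.02 * span))
  fits <- lapply(starts, run_em)
  lls <- vapply(fits, function(f) loglik(f$p11), numeric(1))
  best <- fits[[which.max(lls)]]
  converged <- best$converged
  # EM converges sublinearly at the feasibility boundary; polish the
  # 1-D profile directly and consider the boundaries themselves
  cand <- c(best$p11, lo_p11, hi_p11)
  if (span > 0)
    cand <- c(cand, stats::optimize(loglik, c(lo_p11, hi_p11),
                                    maximum = TRUE, tol = 1e-12)$maximum)
  p11 <- cand[which.max(vapply(cand, loglik, numeric(1)))]
  if (!is.finite(loglik(p11)) && nd > 0) {
    # composite-LD fallback: correlation-based D (degenerate EM state)
    r <- suppressWarnings(cor(a, b))
    p11 <- pA * pB + r * sqrt(pA * (1 - pA) * pB * (1 - pB))
  }
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax <= 0) 0 else D / dmax
  structure(max(-1, min(1, dp)), D = D, em_converged = converged)
}

#' Build the polarization table around an index SNP
#'
#' Computes signed D' between the index SNP and up to `window` SNPs on
#' each side (same chromosome, truncated at its ends) and assigns the
#' polarization mark: 1 when `D' > hi`, -1 when `D' < lo`, 0 otherwise
#' (including undefined D'). The index SNP itself gets mark 1.
#'
#' @param gm a `GenotypeMatrix`.
#' @param index snp_id of the index SNP.
#' @param window SNPs per side (default 80).
#' @param hi,lo mark thresholds (defaults 0.9 / -0.9).
#' @return data.frame of class `PolarizationTable`: `index_snp`,
#'   `neighbor_snp`, `distance_bp`, `dprime`, `mark`.
#' @export
build_polarization_table <- function(gm, index, window = 80,
                                     hi = 0.9, lo = -0.9) {
  stopifnot(inherits(gm, "GenotypeMatrix"), window >= 1)
  i <- match(index, gm$variants$snp_id)
  if (is.na(i)) stop("unknown index SNP: ", index)
  chrom <- gm$variants$chrom[i]
  same <- which(gm$variants$chrom == chrom)
  pos_in_chrom <- match(i, same)
  lo_i <- same[max(1, pos_in_chrom - window)]
  hi_i <- same[min(length(same), pos_in_chrom + window)]
  neigh <- same[same >= lo_i & same <= hi_i]

  g0 <- gm$codes[, i]
  dp <- vapply(neigh, function(j)
    if (j == i) 1 else as.numeric(dprime(g0, gm$codes[, j])), numeric(1))
  mark <- ifelse(is.na(dp), 0L, ifelse(dp > hi, 1L, ifelse(dp < lo, -1L, 0L)))
  mark[neigh == i] <- 1L
  out <- data.frame(index_snp = index,
                    neighbor_snp = gm$variants$snp_id[neigh],
                    distance_bp = gm$variants$pos[neigh] - gm$variants$pos[i],
                    dprime = dp, mark = mark, stringsAsFactors = FALSE)
  class(out) <- c("PolarizationTable", class(out))
  out
}

#' Polarize a DataTable region
#'
#' Inverts the QAS of every test result at SNPs whose polarization mark
#' is -1 (`QAS <- 1 / QAS`); p-values are untouched, mark 0 and 1 rows
#' unchanged. Applying the same polarization twice restores the input.
#'
#' @param table a `DataTable` whose SNPs are covered by `ptable`
#'   (index SNP plus neighbours); SNPs outside the table are ignored.
#' @param ptable a `PolarizationTable` from
#'   [build_polarization_table()].
#' @return the polarized `DataTable`, with attribute `polarized_around`
#'   naming the index SNP.
#' @export
polarize <- function(table, ptable) {
  stopifnot(inherits(table, "DataTable"),
            inherits(ptable, "PolarizationTable"))
  marks <- ptable$mark[match(table$variants$snp_id, ptable$neighbor_snp)]
  flip <- which(!is.na(marks) & marks == -1L)
  if (length(flip))
    table$qas[flip, ] <- 1 / table$qas[flip, , drop = FALSE]
  attr(table, "polarized_around") <- ptable$index_snp[1]
  table
}

#' Write a polarization table as TSV
#'
#' @param ptable a `PolarizationTable`.
#' @param path output path.
#' @export
write_polarization_table <- function(ptable, path) {
  write.table(ptable, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
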