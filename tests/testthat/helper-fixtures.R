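# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (enumeration / grid search /
# double loops) and independent of the package implementation paths.

# tiny variant table
toy_variants <- function(n, chrom = "chr1", start = 1000, step = 500) {
  data.frame(snp_id = sprintf("rs%d", seq_len(n)), chrom = rep(chrom, n),
             pos = as.integer(start + (seq_len(n) - 1) * step),
             allele_major = rep("A", n), allele_minor = rep("G", n),
             stringsAsFactors = FALSE)
}

toy_gm <- function(codes, chrom = "chr1") {
  codes <- as.matrix(codes)
  genotype_matrix(toy_variants(ncol(codes), chrom),
                  paste0("S", seq_len(nrow(codes))), codes)
}

# random DataTable with given shape
random_data_table <- function(n_snps, n_tests, seed, missing_frac = 0) {
  set.seed(seed)
  v <- toy_variants(n_snps)
  v$maf <- runif(n_snps, 0.05, 0.5)
  tests <- data.frame(test_id = sprintf("T%03d", seq_len(n_tests)),
                      family = rep("INF", n_tests),
                      stage = sample(c("I", "II"), n_tests, replace = TRUE),
                      model = rep("D", n_tests),
                      endpoint = rep(NA_character_, n_tests),
                      contrast = rep("SC_HREU", n_tests),
                      breakpoints = rep(NA_character_, n_tests),
                      subset = rep(NA_character_, n_tests),
                      group_id = rep("A", n_tests),
                      stringsAsFactors = FALSE)
  p <- matrix(runif(n_snps * n_tests), n_snps, n_tests)
  qas <- matrix(exp(rnorm(n_snps * n_tests, sd = 0.5)), n_snps, n_tests)
  if (missing_frac > 0) {
    drop <- matrix(runif(n_snps * n_tests) < missing_frac, n_snps, n_tests)
    p[drop] <- NA; qas[drop] <- NA
  }
  data_table(v, tests, p, qas)
}

# brute-force windowed density: literal double loop over SNPs and tests
oracle_density <- function(p, chrom, pos, half_width, mode, aggregate) {
  S <- nrow(p)
  out <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    lanes <- numeric(0)
    for (t in seq_len(ncol(p))) {
      vals <- c()
      for (u in seq_len(S)) {
        if (chrom[u] != chrom[s]) next
        inwin <- if (mode == "snps") {
          same <- which(chrom == chrom[s])
          abs(match(u, same) - match(s, same)) <= half_width
        } else abs(pos[u] - pos[s]) <= half_width * 1000
        if (inwin && !is.na(p[u, t])) vals <- c(vals, -log10(max(p[u, t], 1e-300)))
      }
      if (length(vals)) lanes <- c(lanes, mean(vals))
    }
    if (length(lanes))
      out[s] <- if (aggregate == "mean") mean(lanes) else max(lanes)
  }
  out
}

# grid-search maximum-likelihood D': enumerates haplotype phase mixtures
# implied by each feasible p11 and maximizes the multinomial likelihood
# of the observed two-locus genotype table
oracle_dprime <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  N <- length(a)
  pA <- sum(a) / (2 * N); pB <- sum(b) / (2 * N)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  n <- table(factor(a, 0:2), factor(b, 0:2))
  ll <- function(p11) {
    hap <- c(`00` = 1 - pA - pB + p11, `01` = pB - p11,
             `10` = pA - p11, `11` = p11)
    if (min(hap) < -1e-12) return(-Inf)
    P <- function(ha, hb) hap[[paste0(ha, hb)]]
    s <- 0
    for (ga in 0:2) for (gb in 0:2) {
      gp <- 0
      for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1)
        if (a1 + a2 == ga && b1 + b2 == gb) gp <- gp + P(a1, b1) * P(a2, b2)
      s <- s + n[ga + 1, gb + 1] * log(max(gp, 1e-300))
    }
    s
  }
  grid <- seq(lo, hi, length.out = 2001)
  p11 <- grid[which.max(vapply(grid, ll, numeric(1)))]
  g2 <- seq(max(lo, p11 - (hi - lo) / 1000),
            min(hi, p11 + (hi - lo) / 1000), length.out = 401)
  p11 <- g2[which.max(vapply(g2, ll, numeric(1)))]
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) 0 else max(-1, min(1, D / dmax))
}

# correlated haplotype pair generator for LD fixtures
correlated_codes <- function(n, f1, f2, rho, seed) {
  set.seed(seed)
  h1 <- rbinom(2 * n, 1, f1)
  h2 <- ifelse(runif(2 * n) < abs(rho),
               if (rho > 0) h1 else 1 - h1, rbinom(2 * n, 1, f2))
  list(a = h1[seq(1, 2 * n, 2)] + h1[seq(2, 2 * n, 2)],
       b = h2[seq(1, 2 * n, 2)] + h2[seq(2, 2 * n, 2)])
}

# cohort tables shaped like the published three-group study:
# membership categories overlap, totals are participant counts
study_group_cohort <- function(group = c("B", "C"), id_prefix = group) {
  group <- match.arg(group)
  counts <- list(
    B = list(hreu = 300, osn = 351, sc = 767, sp = 3044, sp_lts = 831,
             sequelae = 1848, haart = 1319),
    C = list(hreu = 148, osn = 267, sc = 288, sp = 757, sp_lts = 170,
             sequelae = 0, haart = 65))[[group]]
  n <- counts$hreu + counts$osn + counts$sc + counts$sp
  rg <- rep(c("HREU", "OSN", "SC", "SP"),
            c(counts$hreu, counts$osn, counts$sc, counts$sp))
  df <- data.frame(sample_id = paste0(id_prefix, seq_len(n)),
                   risk_group = rg, stringsAsFactors = FALSE)
  # SP long-term survivors: followed past 10 years, no early AIDS
  df$AIDS87_time <- NA_real_; df$AIDS87_event <- NA_integer_
  sp_rows <- which(df$risk_group == "SP")
  lts_rows <- sp_rows[seq_len(counts$sp_lts)]
  df$AIDS87_time[sp_rows] <- 5; df$AIDS87_event[sp_rows] <- 1L
  df$AIDS87_time[lts_rows] <- 12; df$AIDS87_event[lts_rows] <- 0L
  # sequelae and HAART memberships among HIV-positive rows
  hiv_rows <- which(df$risk_group %in% c("SC", "SP"))
  df$KS_time <- NA_real_; df$KS_event <- NA_integer_
  if (counts$sequelae > 0) {
    rows <- hiv_rows[seq_len(counts$sequelae)]
    df$KS_time[rows] <- 2; df$KS_event[rows] <- 1L
  }
  df$haart_suppression_time <- NA_real_
  df$haart_suppression_event <- NA_integer_
  if (counts$haart > 0) {
    rows <- hiv_rows[seq_len(counts$haart)]
    df$haart_suppression_time[rows] <- 1; df$haart_suppression_event[rows] <- 0L
  }
  as_cohort_table(df)
}

# single-test DataTable from per-SNP survival scans (polarization studies)
phaz_scan_table <- function(gm, time, event, model = "D") {
  res <- lapply(seq_len(ncol(gm$codes)), function(j)
    phaz_test(gm$codes[, j], time, event, model))
  tests <- data.frame(test_id = "PHAZ_CD4_D", family = "PHAZ", stage = "II",
                      model = model, endpoint = "CD4",
                      contrast = NA_character_,
                      breakpoints = NA_character_, subset = NA_character_,
                      group_id = "SIM", stringsAsFactors = FALSE)
  data_table(gm$variants, tests,
             matrix(vapply(res, `[[`, numeric(1), "p_value"), ncol = 1),
             matrix(vapply(res, `[[`, numeric(1), "qas"), ncol = 1))
}

# one polarization-study replicate: returns TRUE when every strong proxy
# (|D'| > 0.9, p < 0.01) lands on the index SNP's side of QAS = 1 after
# polarization
polarization_rep <- function(seed, n_samples = 2000, n_proxies = 80,
                             hr = 2.5) {
  reg <- simulate_tagged_region(n_samples = n_samples,
                                n_proxies = n_proxies,
                                f_causal = 0.3, seed = seed)
  surv <- simulate_survival(reg$causal_codes, hr, model = "D",
                            baseline = 0.08, censoring_rate = 0.034)
  dt <- phaz_scan_table(reg$gm, surv$time, surv$event)
  top <- top_hits(dt, "logp", k = 1)$snp_id
  pt <- build_polarization_table(reg$gm, top, window = n_proxies)
  dtp <- polarize(dt, pt)
  idx <- match(top, reg$gm$variants$snp_id)
  side_index <- sign(log(dtp$qas[idx, 1]))
  m <- match(reg$gm$variants$snp_id, pt$neighbor_snp)
  strong <- !is.na(pt$dprime[m]) & abs(pt$dprime[m]) > 0.9 &
    dt$p[, 1] < 0.01
  strong[idx] <- FALSE
  if (!any(strong)) return(TRUE)
  all(sign(log(dtp$qas[strong, 1])) == side_index)
}
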