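# Synthetic genotypes with block LD structure and longitudinal HIV-like
# cohorts with planted allelic effects. Everything is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' @param n_samples diploid sample count.
#' @param n_snps number of SNPs (overridden by `ld_blocks` lengths when
#'   given).
#' @param ld_blocks list of `list(length =, dprime =)` blocks; adjacent
#'   SNPs within a block reach the target |D'| via a haplotype copying
#'   process. `NULL` = independent SNPs.
#' @param maf_range minor-allele frequency range to draw from.
#' @param causal list of planted effects, each
#'   `list(snp =, family =, effect =, model =, endpoint =)` with
#'   `effect` an odds ratio (INF) or hazard ratio (survival families).
#' @param risk_group_mix proportions over HREU, OSN, SC, SP (sum 1).
#' @param censoring_rate exponential censoring rate per year.
#' @param baseline_hazard event rate per year for carriers of zero minor
#'   alleles.
#' @param haart_fraction fraction of HIV-positive samples treated.
#' @param sequela_rates named occurrence hazards per condition (defaults
#'   cover all six).
#' @param chrom,start_pos,spacing_bp coordinate layout (default: one
#'   chromosome, 4 kb SNP spacing, matching a dense GWAS array region).
#' @param seed mandatory RNG seed.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_samples = 1000, n_snps = 100,
                              ld_blocks = NULL,
                              maf_range = c(0.05, 0.5),
                              causal = list(),
                              risk_group_mix = c(HREU = 0.1, OSN = 0.1,
                                                 SC = 0.5, SP = 0.3),
                              censoring_rate = 0.05,
                              baseline_hazard = 0.08,
                              haart_fraction = 0.4,
                              sequela_rates = NULL,
                              chrom = "chr2", start_pos = 204000000L,
                              spacing_bp = 4000L, seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(abs(sum(risk_group_mix) - 1) < 1e-9,
            all(names(risk_group_mix) == RISK_GROUPS))
  if (length(causal) && any(vapply(causal, function(x) x$effect, 1) <= 0))
    stop("planted effects must be positive")
  if (!is.null(ld_blocks)) n_snps <- sum(vapply(ld_blocks, `[[`, 1, "length"))
  if (is.null(sequela_rates))
    sequela_rates <- setNames(c(0.03, 0.05, 0.03, 0.02, 0.03, 0.04), SEQUELAE)
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 ld_blocks = ld_blocks, maf_range = maf_range,
                 causal = causal, risk_group_mix = risk_group_mix,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 haart_fraction = haart_fraction,
                 sequela_rates = sequela_rates, chrom = chrom,
                 start_pos = start_pos, spacing_bp = spacing_bp,
                 seed = seed),
            class = "SimulationConfig")
}

#' Simulate an LD-blocked genotype matrix
#'
#' Haplotypes are drawn per block by a copying process: the block draws
#' one ancestral frequency, the first SNP is Bernoulli, and each
#' following SNP copies its left neighbour's allele with probability
#' equal to the block's D' target (else redraws). For a stationary chain
#' this makes the adjacent-pair D' equal the target in expectation, and
#' |D'| decays with SNP distance. Diploids are formed by random pairing
#' of haplotypes; minor-allele anchoring is applied on construction.
#'
#' @param config a [simulation_config()].
#' @return a `GenotypeMatrix`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_samples
  blocks <- config$ld_blocks %||%
    list(list(length = config$n_snps, dprime = 0))
  nh <- 2 * n
  cols <- list()
  for (b in blocks) {
    L <- b$length
    c_target <- b$dprime
    if (c_target < 0 || c_target > 1)
      stop("block D' target must be in [0, 1]")
    f <- runif(1, config$maf_range[1], config$maf_range[2])
    hap <- matrix(0L, nh, L)
    hap[, 1] <- rbinom(nh, 1, f)
    if (L > 1) for (j in 2:L) {
      copy <- runif(nh) < c_target
      hap[, j] <- ifelse(copy, hap[, j - 1], rbinom(nh, 1, f))
    }
    cols[[length(cols) + 1]] <- hap
  }
  hap <- do.call(cbind, cols)
  S <- ncol(hap)
  codes <- hap[seq(1, nh, by = 2), , drop = FALSE] +
    hap[seq(2, nh, by = 2), , drop = FALSE]

  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * S, replace = TRUE),
                    ncol = 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")
  variants <- data.frame(
    snp_id = sprintf("rs%07d", seq_len(S) * 13 + 1000000),
    chrom = config$chrom,
    pos = config$start_pos + (seq_len(S) - 1L) * config$spacing_bp,
    allele_major = alleles[, 1], allele_minor = alleles[, 2],
    stringsAsFactors = FALSE)
  genotype_matrix(variants, sprintf("S%05d", seq_len(n)), codes)
}

#' Simulate a single-causal LD region with coupling and repulsion proxies
#'
#' Builds the canonical polarization test-bed: one causal variant in the
#' middle of a window of proxy SNPs, each proxy tagging the causal
#' haplotype either in coupling (its minor allele rides with the causal
#' minor allele, D' = +1) or in repulsion (its minor allele marks the
#' causal-major background, D' = -1), with tag frequencies thinned so
#' proxies vary in frequency and power.
#'
#' @param n_samples diploid sample count.
#' @param n_proxies proxies around the causal SNP (default 80).
#' @param f_causal causal minor-allele frequency.
#' @param thin_range per-proxy thinning factor range (1 = perfect tag).
#' @param repulsion_prob probability a proxy tags in repulsion.
#' @param seed RNG seed.
#' @param chrom,start_pos,spacing_bp coordinate layout.
#' @return list: `gm` (`GenotypeMatrix`), `causal_id`, `causal_index`,
#'   `orientation` (+1 coupling / -1 repulsion per SNP, causal = +1).
#' @export
simulate_tagged_region <- function(n_samples = 2000, n_proxies = 80,
                                   f_causal = 0.3, thin_range = c(0.6, 1),
                                   repulsion_prob = 0.4, seed,
                                   chrom = "chr2",
                                   start_pos = 204000000L,
                                   spacing_bp = 4000L) {
  set.seed(seed)
  nh <- 2 * n_samples
  h <- rbinom(nh, 1, f_causal)          # causal haplotype allele
  S <- n_proxies + 1
  causal_index <- n_proxies %/% 2 + 1
  hap <- matrix(0L, nh, S)
  orientation <- integer(S)
  for (j in seq_len(S)) {
    if (j == causal_index) {
      hap[, j] <- h
      orientation[j] <- 1L
      next
    }
    g <- runif(1, thin_range[1], thin_range[2])
    if (runif(1) < repulsion_prob) {
      # minor allele rides the causal-major side; its frequency is kept
      # at f_causal * g (below 0.5) so minor-allele anchoring cannot
      # silently flip it back to coupling
      b <- rbinom(nh, 1, g * f_causal / (1 - f_causal))
      hap[, j] <- (1L - h) * b
      orientation[j] <- -1L
    } else {
      b <- rbinom(nh, 1, g)
      hap[, j] <- h * b
      orientation[j] <- 1L
    }
  }
  codes <- hap[seq(1, nh, by = 2), ] + hap[seq(2, nh, by = 2), ]
  variants <- data.frame(
    snp_id = sprintf("rs%07d", seq_len(S) * 17 + 2000000),
    chrom = chrom, pos = start_pos + (seq_len(S) - 1L) * spacing_bp,
    allele_major = "A", allele_minor = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(variants, sprintf("S%05d", seq_len(n_samples)),
                        codes)
  list(gm = gm, causal_id = variants$snp_id[causal_index],
       causal_index = causal_index, orientation = orientation,
       causal_codes = codes[, causal_index])
}

model_dose <- function(codes, model) {
  switch(model,
         D = as.numeric(codes >= 1),
         R = as.numeric(codes == 2),
         CD = , A = as.numeric(codes))
}

#' Simulate a longitudinal HIV-like cohort over a genotype matrix
#'
#' Risk groups are drawn from the configured mix. Infection effects act
#' on the SC-vs-HREU/OSN split through a logistic model with the planted
#' odds ratio; progression and sequelae event times are exponential
#' proportional-hazards draws with the planted hazard ratios; censoring
#' is independent exponential. Among samples with at least one sequela,
#' the earliest occurrence gets the `was_first` flag. A configured
#' fraction of HIV-positive samples is HAART-treated with suppression
#' and rebound outcomes.
#'
#' @param gm a `GenotypeMatrix` from [simulate_genotypes()].
#' @param config the same [simulation_config()] (its `causal` entries
#'   index into `gm` columns).
#' @return a `CohortTable` aligned with `gm$samples`.
#' @export
simulate_cohort <- function(gm, config) {
  stopifnot(inherits(gm, "GenotypeMatrix"),
            inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  n <- length(gm$samples)
  S <- ncol(gm$codes)
  for (cs in config$causal)
    if (cs$snp < 1 || cs$snp > S) stop("causal snp index out of range")

  planted <- function(family, endpoint = NULL) {
    eff <- rep(0, n)   # log-scale linear predictor
    for (cs in config$causal) {
      if (cs$family != family) next
      if (!is.null(endpoint) && !is.null(cs$endpoint) &&
          cs$endpoint != endpoint) next
      x <- model_dose(gm$codes[, cs$snp], cs$model %||% "D")
      x[is.na(x)] <- 0
      eff <- eff + log(cs$effect) * x
    }
    eff
  }

  # serostatus: start from the configured mix, then let planted infection
  # effects reassign the seronegative-at-entry pool (HREU/OSN vs SC)
  groups <- sample(RISK_GROUPS, n, replace = TRUE,
                   prob = config$risk_group_mix)
  inf_eff <- planted("INF")
  if (any(inf_eff != 0)) {
    sn_pool <- groups %in% c("HREU", "OSN", "SC")
    p_mix <- config$risk_group_mix
    base_p <- p_mix[["SC"]] / (p_mix[["HREU"]] + p_mix[["OSN"]] + p_mix[["SC"]])
    logit <- log(base_p / (1 - base_p)) + inf_eff
    p_sc <- 1 / (1 + exp(-logit))
    u <- runif(n)
    newly_sc <- sn_pool & (u < p_sc)
    uninf <- sn_pool & !newly_sc
    groups[newly_sc] <- "SC"
    groups[uninf] <- sample(c("HREU", "OSN"), sum(uninf), replace = TRUE,
                            prob = p_mix[c("HREU", "OSN")] /
                              sum(p_mix[c("HREU", "OSN")]))
  }

  df <- data.frame(sample_id = gm$samples, risk_group = groups,
                   stringsAsFactors = FALSE)
  df$cohort <- sample(c("pooled", "ALIVE", "MACS", "MHCS", "HOMER"),
                      n, replace = TRUE)
  hiv_pos <- groups %in% c("SC", "SP")

  # progression endpoints: exponential PH with planted HR per criterion
  for (crit in AIDS_CRITERIA) {
    lp <- planted("PHAZ", crit)
    rate <- config$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate)
    t_cens <- rexp(n, config$censoring_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time[!hiv_pos] <- NA_real_
    event[!hiv_pos] <- NA_integer_
    df[[paste0(crit, "_time")]] <- round(time, 4)
    df[[paste0(crit, "_event")]] <- event
  }
  df$sp_first_visit_baseline <- ifelse(groups == "SP", TRUE, NA)

  # sequelae: per-condition exponential occurrence among HIV-positive
  seq_times <- matrix(NA_real_, n, length(SEQUELAE),
                      dimnames = list(NULL, SEQUELAE))
  for (cond in SEQUELAE) {
    lp <- planted("SEQ", cond)
    rate <- config$sequela_rates[[cond]] * exp(lp)
    t_event <- rexp(n, rate)
    t_cens <- rexp(n, config$censoring_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time[!hiv_pos] <- NA_real_
    event[!hiv_pos] <- NA_integer_
    df[[paste0(cond, "_time")]] <- round(time, 4)
    df[[paste0(cond, "_event")]] <- event
    seq_times[, cond] <- ifelse(!is.na(event) & event == 1, time, NA_real_)
  }
  # was_first: earliest occurred sequela per sample
  first_idx <- apply(seq_times, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))
  for (ci in seq_along(SEQUELAE)) {
    flag <- rep(NA_integer_, n)
    flag[hiv_pos] <- 0L
    flag[!is.na(first_idx) & first_idx == ci] <- 1L
    df[[paste0(SEQUELAE[ci], "_first")]] <- flag
  }

  # HAART outcomes for a treated subset of HIV-positive samples
  treated <- hiv_pos & runif(n) < config$haart_fraction
  for (ep in HAART_ENDPOINTS) {
    lp <- planted("HAART", ep)
    rate <- 0.15 * exp(lp)
    t_event <- rexp(n, rate)
    t_cens <- rexp(n, config$censoring_rate * 2)
    time <- round(pmin(t_event, t_cens), 4)
    event <- as.integer(t_event <= t_cens)
    time[!treated] <- NA_real_
    event[!treated] <- NA_integer_
    df[[paste0("haart_", ep, "_time")]] <- time
    df[[paste0("haart_", ep, "_event")]] <- event
  }
  as_cohort_table(df)
}

#' Simulate survival times for a planted hazard ratio at one SNP
#'
#' Convenience generator for calibration studies: exponential event
#' times with hazard `baseline * hr^dose`, independent exponential
#' censoring.
#'
#' @param codes dosage codes.
#' @param hr hazard ratio per unit dose.
#' @param model genetic model defining the dose.
#' @param baseline baseline hazard per year.
#' @param censoring_rate censoring hazard per year.
#' @return data.frame with `time` and `event`.
#' @export
simulate_survival <- function(codes, hr, model = "D", baseline = 0.08,
                              censoring_rate = 0.05) {
  x <- model_dose(codes, model)
  x[is.na(x)] <- 0
  t_event <- rexp(length(x), baseline * hr^x)
  t_cens <- rexp(length(x), censoring_rate)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Write the toy fixture suite used by the examples and tests
#'
#' Regenerable byte-identically from the seed: a small genotype TSV and
#' VCF, a clinical CSV, the three group battery configs as YAML, and an
#' 80-proxy single-causal region fixture for polarization demos.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed RNG seed (default 42).
#' @return invisible named list of file paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  cfg <- simulation_config(n_samples = 120, n_snps = 12,
                           ld_blocks = list(list(length = 6, dprime = 0.95),
                                            list(length = 6, dprime = 0.3)),
                           seed = seed)
  gm <- simulate_genotypes(cfg)
  cohort <- simulate_cohort(gm, cfg)
  write_genotypes_tsv(gm, pth("toy_genotypes.tsv"))
  write_vcf(gm, pth("toy_genotypes.vcf"))
  utils::write.csv(cohort, pth("toy_clinical.csv"), row.names = FALSE,
                   na = "")
  for (g in c("A", "B", "C"))
    write_battery_config(hiv_battery_config(g),
                         pth(sprintf("battery_group%s.yaml", g)))
  region <- simulate_tagged_region(n_samples = 400, n_proxies = 80,
                                   f_causal = 0.3, seed = seed + 1)
  write_genotypes_tsv(region$gm, pth("region80_genotypes.tsv"))
  writeLines(jsonlite::toJSON(list(causal_id = region$causal_id,
                                   orientation = region$orientation),
                              auto_unbox = TRUE),
             pth("region80_truth.json"))
  invisible(list(genotypes_tsv = pth("toy_genotypes.tsv"),
                 genotypes_vcf = pth("toy_genotypes.vcf"),
                 clinical = pth("toy_clinical.csv"),
                 configs = pth(sprintf("battery_group%s.yaml",
                                       c("A", "B", "C"))),
                 region = pth("region80_genotypes.tsv")))
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' REF = major allele, ALT = minor allele, unphased diploid GT only.
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$samples),
                     collapse = "\t")), con)
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(gm$codes))) {
    g <- gm$codes[, j]
    gt <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
    writeLines(paste(c(gm$variants$chrom[j], gm$variants$pos[j],
                       gm$variants$snp_id[j], gm$variants$allele_major[j],
                       gm$variants$allele_minor[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
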