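# The association test battery.
#
# Every test reduces to one of two engines:
#   * categorical: genotype (or allele) classes x outcome classes,
#     chi-square with Fisher fallback, Cochran-Armitage trend for the
#     codominant model against a dichotomous outcome;
#   * survival: Cox proportional hazards of event time on the coded
#     genotype, likelihood-ratio p.
# The QAS (Quantitative Association Statistic) is a positive effect
# measure with 1 as the null: the odds ratio for 2x2 tables, the fitted
# relative hazard for survival tests, and the ez2-transformed correlation
# coefficient for larger categorical designs. QAS > 1 means the minor
# allele is associated with the adverse outcome ("susceptible"), QAS < 1
# "resistant".

#' ez2 transform of a correlation coefficient
#'
#' Maps a correlation `r` to the positive, null-at-1 QAS scale:
#' `exp(2 * atanh(r)) = (1 + r) / (1 - r)`. Antisymmetric on the log
#' scale: `ez2_qas(-r) == 1 / ez2_qas(r)`.
#'
#' @param r correlation in (-1, 1).
#' @return positive real; 1 at zero correlation.
#' @export
ez2_qas <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  (1 + r) / (1 - r)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product `(n00 * n11) / (n01 * n10)` with rows = exposure (0, 1)
#' and columns = outcome (0, 1). Any zero cell triggers the
#' Haldane-Anscombe correction (0.5 added to every cell).
#'
#' @param tab 2x2 numeric matrix.
#' @return odds ratio (> 0).
#' @export
odds_ratio <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

assoc_result <- function(p_value, qas, qas_kind, n_used, cells = NULL) {
  if (!is.na(p_value)) p_value <- min(1, max(0, p_value))
  structure(list(p_value = p_value, qas = qas, qas_kind = qas_kind,
                 n_used = n_used, cells = cells, reason = NA_character_),
            class = "AssociationResult")
}

assoc_missing <- function(reason) {
  structure(list(p_value = NA_real_, qas = NA_real_,
                 qas_kind = NA_character_, n_used = 0L, cells = NULL,
                 reason = reason),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  if (is.na(x$p_value))
    cat("AssociationResult: missing (", x$reason, ")\n", sep = "")
  else
    cat(sprintf("AssociationResult: p = %.4g, QAS = %.4g (%s), n = %d\n",
                x$p_value, x$qas, x$qas_kind, x$n_used))
  invisible(x)
}

# Categorical engine. `exposure` and `outcome` are integer class codes
# (ordinal, ascending risk); NA pairs are dropped; empty margins are
# dropped before testing.
categorical_test <- function(exposure, outcome, trend = FALSE) {
  ok <- !is.na(exposure) & !is.na(outcome)
  exposure <- exposure[ok]; outcome <- outcome[ok]
  n <- length(exposure)
  if (!n) return(assoc_missing("no_complete_pairs"))
  tab <- table(factor(exposure), factor(outcome))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(assoc_missing("degenerate_table"))

  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (trend && ncol(tab) == 2) {
    # Cochran-Armitage trend across ordered genotype rows
    scores <- as.numeric(rownames(tab))
    tt <- suppressWarnings(prop.trend.test(tab[, 2], rowSums(tab),
                                           score = scores))
    p <- tt$p.value
  } else if (any(exp_counts < 5)) {
    # exact test, deterministic; fall back to the chi-square when the
    # network algorithm runs out of workspace on a large sparse table
    p <- tryCatch(fisher.test(tab, workspace = 2e6)$p.value,
                  error = function(e)
                    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value))
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }

  if (all(dim(tab) == c(2, 2))) {
    qas <- odds_ratio(tab)
    kind <- "odds_ratio"
  } else {
    # ordinal-by-ordinal correlation on the retained classes
    r <- suppressWarnings(cor(as.numeric(as.character(factor(exposure,
           levels = rownames(tab)))),
         as.numeric(as.character(factor(outcome, levels = colnames(tab)))),
         use = "complete.obs"))
    if (is.na(r) || abs(r) >= 1)
      return(assoc_missing("degenerate_correlation"))
    qas <- ez2_qas(r)
    kind <- "ez2"
  }
  assoc_result(p, qas, kind, n, cells = tab)
}

#' HIV infection association test
#'
#' Categorical test of coded genotype (or allele, model `"A"`) against a
#' serostatus contrast. Seroprevalent (SP) samples are never informative
#' for infection and are excluded.
#'
#' @param codes minor-allele dosage codes, one per sample.
#' @param risk_group risk-group label per sample (HREU/OSN/SC/SP).
#' @param contrast `"SC_HREU"`, `"SC_HREUOSN"` (SC vs HREU+OSN) or
#'   `"SC_HREU_OSN"` (three ordered classes HREU < OSN < SC).
#' @param model genetic model (D/R/CD/A).
#' @return an `AssociationResult`.
#' @export
infection_test <- function(codes, risk_group, contrast = "SC_HREU",
                           model = "CD") {
  stopifnot(length(codes) == length(risk_group))
  if (!contrast %in% INF_CONTRASTS) stop("unknown contrast: ", contrast)
  outcome <- switch(contrast,
    SC_HREU = ifelse(risk_group == "SC", 1L,
                     ifelse(risk_group == "HREU", 0L, NA_integer_)),
    SC_HREUOSN = ifelse(risk_group == "SC", 1L,
                        ifelse(risk_group %in% c("HREU", "OSN"), 0L,
                               NA_integer_)),
    SC_HREU_OSN = ifelse(risk_group == "HREU", 0L,
                         ifelse(risk_group == "OSN", 1L,
                                ifelse(risk_group == "SC", 2L,
                                       NA_integer_))))
  outcome[risk_group == "SP"] <- NA_integer_
  exposure <- code_genotypes(codes, model)
  if (model == "A") outcome <- rep(outcome, each = 2)
  categorical_test(exposure, outcome, trend = FALSE)
}

#' Classify survival data into progression categories (CTSD)
#'
#' Dichotomizes or bins right-censored survival times at breakpoints,
#' with the removal rules of the categorical-tests-for-survival-data
#' approach: individuals censored before the (last) breakpoint cannot be
#' classified and are removed; seroprevalent (SP) individuals failing
#' before the first breakpoint are removed (their baseline is the first
#' visit, not seroconversion, so early failure times are not
#' comparable); everyone censored or failing after the last breakpoint is
#' a long-term survivor (class 0).
#'
#' @param time years from baseline.
#' @param event 1 = failed, 0 = censored.
#' @param risk_group per-sample risk group (SP triggers the early-failure
#'   removal rule).
#' @param breakpoints ordered positive years; length 1 = dichotomous.
#' @return integer vector: 0 for long-term survivors, `j > 0` for failure
#'   in the j-th interval counted backwards from the last breakpoint
#'   (higher = faster progression); `NA` = removed.
#' @export
ctsd_classify <- function(time, event, risk_group, breakpoints) {
  stopifnot(length(time) == length(event),
            length(time) == length(risk_group))
  breakpoints <- sort(breakpoints)
  if (any(breakpoints <= 0)) stop("breakpoints must be positive")
  k <- length(breakpoints)
  last <- breakpoints[k]
  out <- rep(NA_integer_, length(time))
  ev <- !is.na(time) & !is.na(event) & event != 0
  cs <- !is.na(time) & !is.na(event) & event == 0

  # long-term survivors: censored or failed at/after the last breakpoint
  out[(ev | cs) & time >= last] <- 0L
  # failures before the last breakpoint: class by interval, except SP
  # failing before the first breakpoint
  early <- ev & time < last
  if (any(early)) {
    interval <- findInterval(time[early], breakpoints) + 1L  # 1..k
    out[early] <- k + 1L - interval                          # k..1
    sp_early <- early & risk_group %in% "SP" & time < breakpoints[1]
    out[sp_early] <- NA_integer_
  }
  # censored before the last breakpoint stay NA (removed)
  out
}

#' Progression categorical test (PDCA)
#'
#' Contingency test of coded genotype against [ctsd_classify()] classes.
#' Codominant exposure against a dichotomous outcome uses the
#' Cochran-Armitage trend test.
#'
#' @param codes dosage codes per sample.
#' @param classes output of [ctsd_classify()] (NA = removed).
#' @param model genetic model (D/R/CD).
#' @return an `AssociationResult`.
#' @export
pdca_test <- function(codes, classes, model = "CD") {
  exposure <- code_genotypes(codes, model)
  categorical_test(exposure, classes, trend = (model == "CD"))
}

#' Proportional-hazards survival test (PHAZ)
#'
#' Cox proportional-hazards fit of event time on the coded genotype
#' (dominant/recessive carrier indicator, or per-allele 0/1/2 trend for
#' the codominant model). p-value from the likelihood-ratio test; QAS is
#' the fitted relative hazard.
#'
#' @param codes dosage codes per sample (pre-filtered to the analysis
#'   population, e.g. seroconverters only).
#' @param time,event right-censored survival outcome (years; 1 = event).
#' @param model genetic model (D/R/CD).
#' @return an `AssociationResult` with `qas_kind = "relative_hazard"`.
#' @export
phaz_test <- function(codes, time, event, model = "CD") {
  x <- code_genotypes(codes, model)
  if (model == "A") stop("allelic model is not defined for survival tests")
  ok <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- as.numeric(x[ok]); time <- time[ok]; event <- event[ok]
  n <- length(x)
  if (!n) return(assoc_missing("no_complete_pairs"))
  if (sum(event) == 0) return(assoc_missing("no_events"))
  if (length(unique(x)) < 2) return(assoc_missing("monomorphic_exposure"))
  fit <- tryCatch(coxph(Surv(time, event) ~ x),
                  error = function(e) NULL, warning = function(w) {
                    suppressWarnings(coxph(Surv(time, event) ~ x))
                  })
  if (is.null(fit) || is.na(fit$coefficients[1]))
    return(assoc_missing("cox_fit_failed"))
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  res <- assoc_result(p, unname(exp(fit$coefficients[1])),
                      "relative_hazard", n)
  if (abs(fit$coefficients[1]) > 10) res$reason <- "firth_fallback_advised"
  res
}

#' Sequelae association tests
#'
#' Tests whether an AIDS-defining condition (Kaposi's sarcoma, PCP
#' pneumonia, CMV infection, lymphoma, mycobacterial infection, other
#' opportunistic infections) associates with genotype, either for
#' occurrence in any order or for being the first sequela. Survival form
#' (seroconverters only) uses the Cox machinery; categorical form
#' (seroconverters plus seroprevalents) uses the contingency machinery.
#'
#' @param codes dosage codes aligned with `cohort` rows.
#' @param cohort a `CohortTable`.
#' @param condition one of `r toString(SEQUELAE)`.
#' @param order_mode `"any"` (occurred at all) or `"first"` (occurred
#'   first).
#' @param form `"survival"` or `"categorical"`.
#' @param model genetic model (D/R/CD).
#' @return an `AssociationResult`.
#' @export
sequelae_tests <- function(codes, cohort, condition,
                           order_mode = c("any", "first"),
                           form = c("survival", "categorical"),
                           model = "CD") {
  order_mode <- match.arg(order_mode)
  form <- match.arg(form)
  if (!condition %in% SEQUELAE) stop("unknown condition: ", condition)
  tc <- paste0(condition, "_time"); ec <- paste0(condition, "_event")
  fc <- paste0(condition, "_first")
  if (!all(c(tc, ec) %in% names(cohort)))
    return(assoc_missing("condition_not_recorded"))
  occurred <- !is.na(cohort[[ec]]) & cohort[[ec]] != 0
  ev <- if (order_mode == "any") as.integer(occurred) else {
    if (!fc %in% names(cohort)) return(assoc_missing("no_first_flags"))
    as.integer(occurred & !is.na(cohort[[fc]]) & cohort[[fc]] != 0)
  }
  ev[is.na(cohort[[ec]])] <- NA_integer_
  if (form == "survival") {
    sel <- cohort$risk_group %in% "SC"
    phaz_test(codes[sel], cohort[[tc]][sel], ev[sel], model = model)
  } else {
    sel <- cohort$risk_group %in% c("SC", "SP")
    exposure <- code_genotypes(codes[sel], model)
    categorical_test(exposure, ev[sel], trend = (model == "CD"))
  }
}

#' HAART outcome tests
#'
#' Association of genotype with antiretroviral-treatment outcomes:
#' suppression of viral load, or rebound after suppression. Only treated
#' samples (non-missing HAART columns) enter.
#'
#' @param codes dosage codes aligned with `cohort` rows.
#' @param cohort a `CohortTable` with `haart_<endpoint>_time/_event`
#'   columns.
#' @param endpoint `"suppression"` or `"rebound"`.
#' @param form `"survival"` (HRTS) or `"categorical"` (HRTC).
#' @param model genetic model (D/R/CD).
#' @return an `AssociationResult`.
#' @export
haart_tests <- function(codes, cohort, endpoint = c("suppression", "rebound"),
                        form = c("survival", "categorical"), model = "CD") {
  endpoint <- match.arg(endpoint)
  form <- match.arg(form)
  tc <- paste0("haart_", endpoint, "_time")
  ec <- paste0("haart_", endpoint, "_event")
  if (!all(c(tc, ec) %in% names(cohort)))
    return(assoc_missing("endpoint_not_recorded"))
  treated <- !is.na(cohort[[tc]])
  if (!any(treated)) return(assoc_missing("no_treated_samples"))
  if (form == "survival") {
    phaz_test(codes[treated], cohort[[tc]][treated],
              cohort[[ec]][treated], model = model)
  } else {
    exposure <- code_genotypes(codes[treated], model)
    categorical_test(exposure, as.integer(cohort[[ec]][treated]),
                     trend = (model == "CD"))
  }
}
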