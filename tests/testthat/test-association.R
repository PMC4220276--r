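# Battery enumeration and the association test families.

test_that("study-group batteries enumerate the published test counts", {
  a <- enumerate_battery(hiv_battery_config("A"))
  b <- enumerate_battery(hiv_battery_config("B"))
  c_ <- enumerate_battery(hiv_battery_config("C"))
  expect_equal(nrow(a), 123)
  expect_equal(nrow(b), 144)
  expect_equal(nrow(c_), 60)
  expect_equal(nrow(a) + nrow(b) + nrow(c_), 327)
  expect_false(anyDuplicated(a$test_id) > 0)
  # infection rows: 3 contrasts x 4 models for groups B/C
  expect_equal(sum(b$family == "INF"), 12)
  expect_setequal(unique(b$model[b$family == "INF"]),
                  c("D", "R", "CD", "A"))
})

test_that("battery cross-products and count validation behave", {
  # 4 criteria x 3 models survival row
  cfg <- battery_config("X", list(
    battery_row("PHAZ", endpoints = AIDS_CRITERIA,
                models = c("D", "R", "CD"))))
  expect_equal(nrow(enumerate_battery(cfg)), 12)
  # empty config
  expect_equal(nrow(enumerate_battery(battery_config("X", list(
    battery_row("PHAZ", endpoints = character(0), models = character(0)))))),
    0)
  # expected_count mismatch errors and lists the enumeration
  bad <- battery_config("X", list(
    battery_row("PHAZ", endpoints = "CD4", models = "D",
                expected_count = 5)))
  expect_error(enumerate_battery(bad), "expected 5")
  # totals are additive over rows
  cfg2 <- battery_config("X", list(
    battery_row("PHAZ", endpoints = AIDS_CRITERIA, models = "D"),
    battery_row("SEQSA", endpoints = SEQUELAE, models = c("D", "R"))))
  expect_equal(nrow(enumerate_battery(cfg2)), 4 + 12)
})

test_that("battery rows validate their axes", {
  expect_error(battery_row("INF"), "contrasts")
  expect_error(battery_row("PHAZ", endpoints = "CD4", models = "A"),
               "allelic")
  expect_error(battery_row("PDCA2", endpoints = "CD4",
                           breakpoints = list(c(3, 7))), "exactly one")
  expect_error(battery_row("PDCAM", endpoints = "CD4",
                           breakpoints = list(7)), "at least two")
})

test_that("battery configs round-trip through YAML", {
  cfg <- hiv_battery_config("A")
  tf <- tempfile(fileext = ".yaml")
  write_battery_config(cfg, tf)
  cfg2 <- read_battery_config(tf)
  expect_equal(enumerate_battery(cfg2), enumerate_battery(cfg))
})

test_that("odds ratio is the ad/bc cross-product with Haldane fallback", {
  expect_equal(odds_ratio(matrix(c(10, 20, 20, 10), 2, byrow = TRUE)),
               0.25)
  # zero cell: 0.5 added everywhere before the cross-product
  tab <- matrix(c(0, 10, 15, 5), 2, byrow = TRUE)
  expect_equal(odds_ratio(tab), (0.5 * 5.5) / (10.5 * 15.5))
  # property: matches brute force on random zero-free tables
  set.seed(51)
  for (i in 1:50) {
    m <- matrix(sample(1:50, 4), 2)
    expect_identical(odds_ratio(m), (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
  }
})

test_that("ez2 transform maps correlations onto the QAS scale", {
  expect_equal(ez2_qas(0), 1)
  expect_equal(ez2_qas(0.5), 3)
  set.seed(52)
  r <- runif(20, -0.99, 0.99)
  expect_equal(ez2_qas(-r), 1 / ez2_qas(r))
  expect_equal(ez2_qas(r), exp(2 * atanh(r)))
  expect_error(ez2_qas(1), "< 1")
})

test_that("infection test builds the right contrasts and QAS", {
  rg <- c(rep("SC", 30), rep("HREU", 30), rep("OSN", 20), rep("SP", 20))
  g <- c(rep(0, 10), rep(1, 10), rep(2, 10),   # SC
         rep(0, 20), rep(1, 10),               # HREU
         rep(0, 20), rep(2, 20))               # OSN, SP
  res <- infection_test(g, rg, "SC_HREU", "D")
  expect_equal(res$n_used, 60)                  # SP and OSN excluded
  # exposure x outcome: rows HREU (0:20,1:10), SC (0:10,1:20)
  expect_equal(res$qas, (20 * 20) / (10 * 10))
  res2 <- infection_test(g, rg, "SC_HREUOSN", "D")
  expect_equal(res2$n_used, 80)
  res3 <- infection_test(g, rg, "SC_HREU_OSN", "CD")
  expect_equal(res3$qas_kind, "ez2")
  # allelic model doubles the observations
  res4 <- infection_test(g, rg, "SC_HREU", "A")
  expect_equal(res4$n_used, 120)
  # degenerate: everyone the same genotype
  res5 <- infection_test(rep(0, 100), rg, "SC_HREU", "D")
  expect_true(is.na(res5$p_value))
  expect_equal(res5$reason, "degenerate_table")
})

test_that("CTSD classification applies the removal rules", {
  # three seroconverters around a 7-year breakpoint
  cls <- ctsd_classify(time = c(3, 12, 12), event = c(1, 1, 0),
                       risk_group = rep("SC", 3), breakpoints = 7)
  expect_equal(cls, c(1L, 0L, 0L))   # progressor, LTS, LTS
  # SP failing before the breakpoint is removed
  expect_true(is.na(ctsd_classify(3, 1, "SP", 7)))
  # censored before the breakpoint is removed
  expect_true(is.na(ctsd_classify(3, 0, "SC", 7)))
  # SC failing before the breakpoint stays
  expect_equal(ctsd_classify(3, 1, "SC", 7), 1L)
})

test_that("multipoint CTSD bins failures by breakpoint interval", {
  bp <- c(3, 7, 11)
  # failures at 1, 5, 9 years: fastest progression gets the highest class
  expect_equal(ctsd_classify(c(1, 5, 9), c(1, 1, 1), rep("SC", 3), bp),
               c(3L, 2L, 1L))
  # censored after the last breakpoint joins the long-term survivors
  expect_equal(ctsd_classify(12, 0, "SC", bp), 0L)
  # censored inside the grid cannot be classified
  expect_true(is.na(ctsd_classify(5, 0, "SC", bp)))
  # SP failing before the first breakpoint removed; later failures kept
  expect_true(is.na(ctsd_classify(1, 1, "SP", bp)))
  expect_equal(ctsd_classify(5, 1, "SP", bp), 2L)
})

test_that("PDCA on a perfectly balanced table is null", {
  g <- rep(c(0, 1), each = 40)
  cls <- rep(c(0L, 1L), 40)
  res <- pdca_test(g, cls, "D")
  expect_equal(res$qas, 1)
  expect_gt(res$p_value, 0.99)
})

test_that("survival test recovers null and degenerate cases", {
  set.seed(53)
  g <- rbinom(300, 2, 0.3)
  d <- simulate_survival(g, hr = 1, model = "D")
  res <- phaz_test(g, d$time, d$event, "D")
  expect_equal(res$qas_kind, "relative_hazard")
  expect_gt(res$p_value, 0.001)   # no effect planted
  # all censored: no information
  res2 <- phaz_test(g, d$time, rep(0, 300), "D")
  expect_equal(res2$reason, "no_events")
  # monomorphic exposure
  res3 <- phaz_test(rep(1, 300), d$time, d$event, "D")
  expect_equal(res3$reason, "monomorphic_exposure")
})

test_that("sequelae tests count any-order and first-order events", {
  n <- 10
  coh <- as_cohort_table(data.frame(
    sample_id = paste0("S", 1:n),
    risk_group = c(rep("SC", 6), rep("SP", 4)),
    KS_time = c(1, 2, 3, 5, 5, 5, 2, 5, 5, 5),
    KS_event = c(1, 1, 0, 0, 0, 0, 1, 0, 0, 0),
    KS_first = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE))
  g <- rep(c(0, 1), 5)
  # any order: 3 occurrences; first order: 1
  any_ev <- !is.na(coh$KS_event) & coh$KS_event == 1
  expect_equal(sum(any_ev), 3)
  expect_equal(sum(coh$KS_first == 1), 1)
  res_cat <- sequelae_tests(g, coh, "KS", "any", "categorical", "D")
  expect_equal(res_cat$n_used, 10)       # SC + SP
  res_surv <- sequelae_tests(g, coh, "KS", "any", "survival", "D")
  expect_equal(res_surv$n_used, 6)       # SC only
  # zero first-occurrences in the SC stratum -> no events -> missing
  coh2 <- coh; coh2$KS_first <- 0
  res_first <- sequelae_tests(g, coh2, "KS", "first", "survival", "D")
  expect_true(is.na(res_first$p_value))
})

test_that("HAART tests run on the treated subset only", {
  coh <- as_cohort_table(data.frame(
    sample_id = paste0("S", 1:8), risk_group = rep("SC", 8),
    haart_suppression_time = c(1, 2, 1, 3, NA, NA, NA, NA),
    haart_suppression_event = c(1, 0, 1, 0, NA, NA, NA, NA),
    stringsAsFactors = FALSE))
  g <- c(0, 1, 2, 1, 0, 1, 2, 0)
  res <- haart_tests(g, coh, "suppression", "categorical", "D")
  expect_equal(res$n_used, 4)
  res2 <- haart_tests(g, coh, "rebound", "categorical", "D")
  expect_equal(res2$reason, "endpoint_not_recorded")
  coh$haart_suppression_time <- NA_real_
  res3 <- haart_tests(g, coh, "suppression", "survival", "D")
  expect_true(is.na(res3$p_value))
})

test_that("run_battery fills the grid deterministically", {
  cfg <- simulation_config(n_samples = 150, n_snps = 6, seed = 61)
  gm <- simulate_genotypes(cfg)
  cohort <- simulate_cohort(gm, cfg)
  tests <- enumerate_battery(hiv_battery_config("A"))[1:20, ]
  dt1 <- run_battery(gm, cohort, tests)
  dt2 <- run_battery(gm, cohort, tests)
  f1 <- tempfile(); f2 <- tempfile()
  write_data_table(dt1, f1); write_data_table(dt2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(dim(dt1), c(6L, 20L))

  # empty cohort: all cells missing with reasons
  empty <- cohort[0, ]
  dt0 <- run_battery(gm, empty, tests)
  expect_true(all(is.na(dt0$p)))
  expect_true(all(!is.na(dt0$reason)))
})

test_that("a battery shaped like study group A yields 123 test columns", {
  cfg <- simulation_config(n_samples = 120, n_snps = 3, seed = 62)
  gm <- simulate_genotypes(cfg)
  cohort <- simulate_cohort(gm, cfg)
  dt <- run_battery(gm, cohort, hiv_battery_config("A"))
  expect_equal(ncol(dt$p), 123)
})

test_that("planted dominant effects surface with the right QAS side", {
  set.seed(63)
  # risk-increasing minor allele: QAS > 1 in categorical and survival
  g <- rbinom(800, 2, 0.3)
  lin <- log(3) * (g >= 1)
  pr <- 1 / (1 + exp(-(qlogis(0.3) + lin)))
  rg <- ifelse(runif(800) < pr, "SC", "HREU")
  expect_gt(infection_test(g, rg, "SC_HREU", "D")$qas, 1)
  d <- simulate_survival(g, hr = 2.5, model = "D")
  expect_gt(phaz_test(g, d$time, d$event, "D")$qas, 1)
  # protective allele: QAS < 1
  d2 <- simulate_survival(g, hr = 0.4, model = "D")
  expect_lt(phaz_test(g, d2$time, d2$event, "D")$qas, 1)
})
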