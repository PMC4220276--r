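# Snapshots, TRAX documents and the region JSON export. The testable
# surface is the sidecar files; images only need to exist and be stable.

make_report_inputs <- function(seed = 101, n_samples = 150, n_snps = 8) {
  cfg <- simulation_config(n_samples = n_samples, n_snps = n_snps,
                           seed = seed)
  gm <- simulate_genotypes(cfg)
  cohort <- simulate_cohort(gm, cfg)
  dt <- suppressWarnings(run_battery(gm, cohort,
                                     hiv_battery_config("A")))
  list(gm = gm, cohort = cohort, dt = dt)
}

test_that("region queries resolve by coordinates, rs-number and gene", {
  dt <- random_data_table(10, 2, seed = 100)
  sel <- resolve_region(dt, region_query(chrom = "chr1", start = 1000,
                                         end = 2500))
  expect_equal(sel, 1:4)
  sel2 <- resolve_region(dt, region_query(snp_id = "rs3", flank_bp = 600))
  expect_true(3 %in% sel2 && all(abs(dt$variants$pos[sel2] -
                                     dt$variants$pos[3]) <= 600))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tGENE1", bed)
  sel3 <- resolve_region(dt, region_query(gene = "GENE1", genes_bed = bed))
  expect_equal(sel3, 1:3)
  expect_error(region_query(snp_id = "rs1", gene = "G"), "exactly one")
  expect_error(resolve_region(dt, region_query(chrom = "chr9", start = 1,
                                               end = 2)), "no SNPs")
})

test_that("region strings parse with thousands separators", {
  rq <- parse_region("chr2:204,000,000-205,000,000")
  expect_equal(rq$chrom, "chr2")
  expect_equal(rq$start, 204000000L)
  expect_equal(rq$end, 205000000L)
  expect_error(parse_region("chr2-204"), "cannot parse")
})

test_that("cell styling bins p-values and colors QAS directions", {
  sc <- color_scale(p_bins = c(0.05, 1e-2, 1e-4, 1e-6))
  st <- cell_style(c(0.2, 0.03, 1e-6, NA), c(0.5, 2, 1, 3), sc)
  expect_equal(st$bin, c(0L, 1L, 4L, NA))      # grey bin above 0.05
  expect_equal(st$hue, c("green", "red", "neutral", "red"))
  # equal |log QAS| gives equal intensity, opposite hue
  st2 <- cell_style(c(1e-3, 1e-3), c(2, 0.5), color_scale())
  expect_equal(st2$intensity[1], st2$intensity[2])
  expect_equal(st2$hue, c("red", "green"))
  # intensity is a pure monotone function of |log10 QAS|
  set.seed(102)
  q <- exp(runif(50, -2, 2))
  st3 <- cell_style(rep(1e-3, 50), q, color_scale())
  expect_equal(order(st3$intensity), order(abs(log10(q))))
  expect_error(color_scale(p_bins = c(0.05, 0.1)), "decreasing")
})

test_that("2D snapshot covers the region grid and mirrors the table", {
  dt <- random_data_table(80, 123, seed = 103, missing_frac = 0.02)
  rq <- region_query(chrom = "chr1", start = 1, end = 10^9)
  out <- tempfile(fileext = ".png")
  cells <- snapshot_2d(dt, rq, out_path = out)
  expect_equal(nrow(cells), 80 * 123)          # ~10,000 SNP-test combos
  expect_true(file.exists(out))
  side <- read.table(paste0(out, ".cells.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(side), 80 * 123)
  # sidecar numbers equal the DataTable cells exactly
  idx <- cbind(match(side$snp_id, dt$variants$snp_id),
               match(side$test_id, dt$tests$test_id))
  expect_equal(side$p, unname(dt$p[idx]))
  expect_equal(side$qas, unname(dt$qas[idx]))
})

test_that("3D snapshot heights equal the JSON export heights", {
  dt <- random_data_table(5, 3, seed = 104)
  rq <- region_query(chrom = "chr1", start = 1, end = 10^9)
  out <- tempfile(fileext = ".png")
  blocks <- snapshot_3d(dt, rq, out_path = out)
  expect_equal(blocks$height, -log10(pmax(
    dt$p[cbind(match(blocks$snp_id, dt$variants$snp_id),
               match(blocks$test_id, dt$tests$test_id))], 1e-300)))
  js <- export_region_json(dt, rq)
  expect_equal(js$schema, "gwascan-region/1")
  expect_equal(js$n_snps, 5)
  flat <- unlist(lapply(js$snps, function(s)
    vapply(s$tests, `[[`, numeric(1), "height")))
  expect_equal(unname(flat), blocks$height[order(match(blocks$snp_id,
    dt$variants$snp_id))])
  # 3 SNPs x 2 tests -> 6 block records
  js2 <- export_region_json(random_data_table(3, 2, seed = 105), rq)
  expect_equal(sum(lengths(lapply(js2$snps, `[[`, "tests"))), 6)
})

test_that("polarized and plain snapshots differ only at mark -1 rows", {
  dt <- random_data_table(6, 4, seed = 106)
  pt <- data.frame(index_snp = "rs3", neighbor_snp = paste0("rs", 1:6),
                   distance_bp = 0, dprime = c(1, -1, 1, 0, -1, 0.5),
                   mark = c(1L, -1L, 1L, 0L, -1L, 0L),
                   stringsAsFactors = FALSE)
  class(pt) <- c("PolarizationTable", class(pt))
  rq <- region_query(chrom = "chr1", start = 1, end = 10^9)
  o1 <- tempfile(fileext = ".png"); o2 <- tempfile(fileext = ".png")
  plain <- snapshot_3d(dt, rq, out_path = o1)
  pol <- snapshot_3d(dt, rq, polarized = TRUE, ptable = pt, out_path = o2)
  changed <- plain$qas != pol$qas
  flipped_snps <- unique(plain$snp_id[changed])
  expect_setequal(flipped_snps, c("rs2", "rs5"))
  expect_equal(plain$p, pol$p)
})

test_that("Manhattan plots render deterministically", {
  dt <- random_data_table(40, 2, seed = 107)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  manhattan(dt, dt$tests$test_id[1], f1)
  manhattan(dt, dt$tests$test_id[1], f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(manhattan(dt, "nope", tempfile()), "unknown test")
})

test_that("TRAX page lists every test and matches the table exactly", {
  inp <- make_report_inputs()
  snp <- inp$gm$variants$snp_id[3]
  out <- tempfile(fileext = ".html")
  summ <- trax_page(inp$gm, inp$cohort, inp$dt, snp, out)
  expect_equal(nrow(summ), 123)
  side <- read.table(paste0(out, ".tests.tsv"), header = TRUE, sep = "\t",
                     colClasses = "character")
  expect_equal(nrow(side), 123)
  s <- match(snp, inp$dt$variants$snp_id)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  expect_identical(num(side$p), unname(inp$dt$p[s, ]))
  expect_identical(num(side$qas), unname(inp$dt$qas[s, ]))
  # missing cells stay in the document as NA rows
  expect_equal(sum(is.na(side$p)), sum(is.na(inp$dt$p[s, ])))
  # header MAF equals compute_maf on the genotype column
  html <- paste(readLines(out), collapse = "\n")
  maf <- as.numeric(compute_maf(inp$gm$codes[, 3]))
  expect_true(grepl(sprintf("%.17g", maf), html, fixed = TRUE))
  expect_error(trax_page(inp$gm, inp$cohort, inp$dt, "rsNOPE", out),
               "unknown SNP")
})

test_that("TRAX report backs tests with contingency tables and KM curves", {
  inp <- make_report_inputs()
  snp <- inp$gm$variants$snp_id[2]
  out <- tempfile(fileext = ".html")
  rep <- trax_report(inp$gm, inp$cohort, inp$dt, snp, out)
  surv_fams <- c("PHAZ", "SEQSA", "SEQS1", "HRTS")
  cont_fams <- unique(sub("_.*", "", rep$contingency$test_id))
  km_fams <- unique(sub("_.*", "", rep$km$test_id))
  # every categorical family with a computable table appears; survival
  # families appear only among the KM sections
  expect_true(length(cont_fams) > 0 && !any(cont_fams %in% surv_fams))
  expect_true(length(km_fams) > 0 && all(km_fams %in% surv_fams))
  # KM sections exist for every survival test with data
  expect_true(all(table(rep$km$test_id) > 0))
  expect_true(file.exists(paste0(out, ".km.tsv")))
  expect_true(file.exists(paste0(out, ".contingency.tsv")))
})

test_that("Kaplan-Meier estimates match the hand-computed product limit", {
  # three subjects, all events at 1, 2, 3 years: steps 2/3, 1/3, 0
  km <- km_by_genotype(time = c(1, 2, 3), event = c(1, 1, 1),
                       codes = c(0, 0, 0))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(1, 2, 3))
  # censored-only stratum: flat at 1
  km2 <- km_by_genotype(time = c(1, 2), event = c(0, 0), codes = c(1, 1))
  expect_true(all(km2$surv == 1))
  # strata are the three genotypes
  km3 <- km_by_genotype(time = rep(1:3, 3), event = rep(1, 9),
                        codes = rep(0:2, each = 3))
  expect_setequal(unique(km3$genotype), 0:2)
})
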