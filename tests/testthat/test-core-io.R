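# Readers/writers and the core containers.

test_that("TSV genotypes read with per-column MAF recomputation", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos\tmajor\tminor\tS1",
               "rs1\tchr1\t100\tA\tG\t0",
               "rs2\tchr1\t200\tA\tG\t1",
               "rs3\tchr1\t300\tA\tG\t2"), tf)
  gm <- read_genotypes(tf, "tsv")
  expect_s3_class(gm, "GenotypeMatrix")
  # one sample: code 2 means the "minor" allele is actually fixed -> the
  # constructor flips it to keep MAF <= 0.5
  expect_equal(gm$variants$maf, c(0, 0.5, 0))
  expect_equal(unname(gm$codes[1, ]), c(0L, 1L, 0L))
})

test_that("VCF sites with majority ALT are flipped to minor-allele codes", {
  tf <- tempfile(fileext = ".vcf")
  gt <- c(rep("1/1", 3), rep("0/1", 2), rep("0/0", 0))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", paste0("S", 1:5)),
                     collapse = "\t"),
               paste(c("chr1", "100", "rs1", "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t")), tf)
  gm <- read_genotypes(tf, "vcf")
  # ALT frequency 8/10 = 0.8 -> flip: REF becomes the minor allele
  expect_equal(gm$variants$maf[1], 0.2)
  expect_equal(gm$variants$allele_minor[1], "A")
  expect_equal(gm$variants$allele_major[1], "G")
  expect_true(mean(gm$codes[, 1]) <= 1)
})

test_that("multi-allelic and indel VCF records are skipped with a count", {
  tf <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"))
  recs <- vapply(1:10, function(i) {
    alt <- if (i == 5) "G,T" else "G"
    paste(c("chr1", 100 * i, paste0("rs", i), "A", alt, ".", "PASS", ".",
            "GT", "0/1", "0/0"), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), tf)
  gm <- read_genotypes(tf, "vcf")
  expect_equal(nrow(gm$variants), 9)
  expect_equal(attr(gm, "skipped"), 1)
})

test_that("unsorted or duplicated coordinates are rejected by name", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos\tmajor\tminor\tS1",
               "rs1\tchr1\t300\tA\tG\t0",
               "rs2\tchr1\t100\tA\tG\t1"), tf)
  expect_error(read_genotypes(tf, "tsv"), "not sorted")
  writeLines(c("snp_id\tchrom\tpos\tmajor\tminor\tS1",
               "rs1\tchr1\t100\tA\tG\t0",
               "rs2\tchr1\t100\tA\tG\t1"), tf)
  expect_error(read_genotypes(tf, "tsv"), "duplicate coordinate")
})

test_that("genotype TSV writer/reader round-trips randomized matrices", {
  set.seed(31)
  for (rep in 1:3) {
    codes <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                           prob = c(.4, .3, .2, .1)), 10, 6)
    # keep every column polymorphic-ish and below 0.5 so no flip occurs
    codes[1, ] <- 0L; codes[2, ] <- 0L; codes[3, ] <- 1L
    gm <- toy_gm(codes)
    tf <- tempfile(fileext = ".tsv")
    write_genotypes_tsv(gm, tf)
    gm2 <- read_genotypes(tf, "tsv")
    expect_equal(gm2$codes, gm$codes)
    expect_equal(gm2$variants$maf, gm$variants$maf)
  }
})

test_that("cohort reader parses risk groups and rejects bad rows", {
  tf <- tempfile(fileext = ".csv")
  df <- data.frame(sample_id = paste0("S", 1:6),
                   risk_group = c("SC", "SC", "HREU", "HREU", "OSN", "SP"),
                   CD4_time = c(1, 2, 3, 4, 5, 6),
                   CD4_event = c(1, 0, 0, 0, 0, 1))
  write.csv(df, tf, row.names = FALSE)
  coh <- read_cohort(tf)
  expect_s3_class(coh, "CohortTable")
  expect_equal(as.vector(table(coh$risk_group)[c("SC", "HREU", "OSN", "SP")]),
               c(2L, 2L, 1L, 1L))

  df2 <- df; df2$risk_group[1] <- "UNKNOWN"
  write.csv(df2, tf, row.names = FALSE)
  expect_error(read_cohort(tf), "unknown risk_group")

  df3 <- df; df3$CD4_time[1] <- NA  # event = 1 without a time
  write.csv(df3, tf, row.names = FALSE)
  expect_error(read_cohort(tf), "event without time")

  df4 <- df; df4$CD4_time[2] <- -1
  write.csv(df4, tf, row.names = FALSE)
  expect_error(read_cohort(tf), "negative time")

  df5 <- df
  df5$KS_time <- 1; df5$KS_event <- 1L; df5$KS_first <- c(1, rep(0, 5))
  df5$PCP_time <- 1; df5$PCP_event <- 1L; df5$PCP_first <- c(1, rep(0, 5))
  write.csv(df5, tf, row.names = FALSE)
  expect_error(read_cohort(tf), "more than one sequela")
})

test_that("DataTable TSV round-trips to 6 significant digits", {
  dt <- random_data_table(2, 2, seed = 5)
  tf <- tempfile(fileext = ".tsv")
  write_data_table(dt, tf)
  dt2 <- read_data_table(tf)
  expect_equal(dt2$p, dt$p, tolerance = 1e-6)
  expect_equal(dt2$qas, dt$qas, tolerance = 1e-6)
  expect_equal(dt2$tests$test_id, dt$tests$test_id)

  # missing cells round-trip through the NA sentinel
  dt$p[1, 2] <- NA; dt$qas[1, 2] <- NA
  write_data_table(dt, tf)
  dt3 <- read_data_table(tf)
  expect_true(is.na(dt3$p[1, 2]) && is.na(dt3$qas[1, 2]))
  raw <- readLines(tf)
  expect_match(raw[2], "\tNA\t")
})

test_that("DataTable TSV layout: 80 SNPs x 123 tests", {
  dt <- random_data_table(80, 123, seed = 6)
  tf <- tempfile(fileext = ".tsv")
  write_data_table(dt, tf)
  raw <- readLines(tf)
  expect_length(raw, 81)  # header + 80 data rows
  expect_length(strsplit(raw[1], "\t")[[1]], 4 + 2 * 123)
})

test_that("reader rejects a mismatched descriptor sidecar", {
  dt <- random_data_table(3, 2, seed = 7)
  tf <- tempfile(fileext = ".tsv")
  write_data_table(dt, tf)
  tj <- jsonlite::read_json(paste0(tf, ".tests.json"), simplifyVector = TRUE)
  tj$test_id <- rev(tj$test_id)
  jsonlite::write_json(tj, paste0(tf, ".tests.json"), dataframe = "rows")
  expect_error(read_data_table(tf), "sidecar does not match")
})

test_that("cohort summaries combine disjoint groups additively", {
  b <- study_group_cohort("B", "b")
  c_ <- study_group_cohort("C", "c")
  tab <- summarize_cohorts(list(B = b, C = c_), combine = c("B", "C"))
  expect_equal(tab$combined[tab$category == "HREU"], 448)
  expect_equal(tab$combined[tab$category == "Total"], 5922)
  expect_equal(tab$B[tab$category == "Total"], 4462)
  expect_equal(tab$C[tab$category == "Total"], 1460)
  # additivity over an arbitrary partition of one table
  half1 <- b[seq_len(2000), ]; half2 <- b[-seq_len(2000), ]
  t2 <- summarize_cohorts(list(H1 = half1, H2 = half2, B = b),
                          combine = c("H1", "H2"))
  expect_equal(t2$combined, t2$B)
})

test_that("overlapping groups declared disjoint are an error", {
  b <- study_group_cohort("B", "x")
  c_ <- study_group_cohort("C", "x")  # shares sample ids with b
  expect_error(summarize_cohorts(list(B = b, C = c_), combine = c("B", "C")),
               "disjoint")
})

test_that("empty cohort list yields an empty summary", {
  expect_equal(nrow(summarize_cohorts(list())), 0)
})
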