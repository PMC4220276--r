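# gwascan

Multi-test GWAS association tables with LD polarization, windowed
density scoring, and per-SNP reports.

## The problem

Genome-wide association studies of complex diseases with rich clinical
follow-up — the motivating case is HIV/AIDS cohort studies with four
disease stages (infection, progression, AIDS-defining conditions,
antiretroviral-treatment response) — produce not one test per SNP but a
whole *battery*: categorical serostatus contrasts, right-censored
survival endpoints under several AIDS criteria, sequelae outcomes, and
treatment-response endpoints, each under several genetic models. The
result of such a screen is a **Data Table**: for every SNP and every
test, a p-value and a **Quantitative Association Statistic (QAS)** — a
positive effect measure with 1 as the null (odds ratio for 2×2 designs,
relative hazard for survival tests, the ez2-transformed correlation
`(1 + r)/(1 − r)` otherwise), where QAS > 1 reads "susceptible" and
QAS < 1 "resistant".

`gwascan` builds that table from genotype (VCF/TSV) and clinical (CSV)
data and then applies a discovery layer on top of it:

- **Polarization** — QAS direction is anchored to the *minor* allele at
  each locus, so a single causal signal shows discordant directions at
  proxy SNPs whose minor allele tags the causal-major haplotype.
  Signed D′ (EM haplotype frequencies from unphased genotypes) is
  computed for 80 SNPs on each side of an index SNP; neighbours with
  D′ > 0.9 get mark 1, D′ < −0.9 mark −1, and QAS values at mark −1
  rows are inverted (`1/QAS`) so a real regional signal shows one
  color.
- **Density** — per SNP and per test, the mean −log10 p over a window
  (n SNPs or n Kbp per side), aggregated across tests (or across the
  tests of one disease stage) by mean or max: a region-level hit score
  robust to isolated artifacts.
- **Top hits** — ranking by extreme −log10 p, by |log QAS|, or by
  density.
- **Reports** — Manhattan plots, 2D heat and 3D checkerboard region
  snapshots (grey above p = 0.05, richer colors for smaller p; green =
  resistant, red = susceptible), per-SNP TRAX documents with every test
  result, contingency bar plots and per-genotype Kaplan–Meier curves,
  and a versioned JSON region export. Every number in a report is
  carried in a machine-readable sidecar and equals its Data Table cell
  exactly.

Statistical engines: chi-square with deterministic Fisher fallback and
Cochran–Armitage trend for categorical tests (including the
categorical-tests-for-survival-data classification with its breakpoint
removal rules), Cox proportional hazards (likelihood-ratio p) for
survival tests, exact-conditional (mid-p) Hardy–Weinberg QC. Genetic
models: dominant, recessive, codominant, allelic.

A synthetic-data module simulates LD-blocked diploid genotypes and
longitudinal HIV-like cohorts with planted odds/hazard ratios, so the
whole pipeline is testable without patient data.

## Worked example

Simulate a 30-SNP region (one 15-SNP high-LD block containing a planted
dominant hazard ratio of 2.5 on the CD4<200 endpoint, one low-LD
block), run the 123-test group-A battery, and rank density peaks:

```r
library(gwascan)

cfg <- simulation_config(
  n_samples = 500, n_snps = 30,
  ld_blocks = list(list(length = 15, dprime = 0.95),
                   list(length = 15, dprime = 0.2)),
  causal = list(list(snp = 8, family = "PHAZ", endpoint = "CD4",
                     effect = 2.5, model = "D")),
  seed = 20)
gm  <- simulate_genotypes(cfg)
coh <- simulate_cohort(gm, cfg)
gm  <- apply_qc(gm)
dt  <- run_battery(gm, coh, hiv_battery_config("A"))
dt
#> DataTable: 30 SNPs x 123 tests (97% cells filled)

top_hits(dt, "density", k = 3,
         spec = density_spec(half_width = 5, aggregate = "max"))
#>  rank    snp_id chrom       pos criterion    score               best_test
#>     1 rs1000013  chr2 204000000   density 2.475664 PDCAM_AIDS87_D_bp3-7-11
#>     2 rs1000026  chr2 204004000   density 2.322216 PDCAM_AIDS87_D_bp3-7-11
#>     3 rs1000143  chr2 204040000   density 2.270725      PHAZ_AIDS93_R_MHCS
```

The top density peaks sit inside the causal LD block (SNPs 1–15): the
planted survival effect at SNP 8 bleeds into its proxies through both
the multipoint progression tests and the Cox survival tests. Polarize
the region around the top peak and read one cell:

```r
pt  <- build_polarization_table(gm, "rs1000013", window = 15)
table(pt$mark)
#>  0  1
#> 13  3
dtp <- polarize(dt, pt)
```

Here three neighbours exceed D′ = 0.9 (mark 1, left as-is), none are in
repulsion (mark −1 would invert their QAS), and the rest are below the
threshold (mark 0, untouched). The index cell itself:

```r
#> index SNP rs1000013: p = 0.0225, hazard ratio QAS = 1.47
```

— a nominally significant, susceptible-direction proxy of the planted
effect: exactly the kind of sub-genome-wide candidate the density
screen is designed to surface for replication.

Render artifacts and a shareable region export:

```r
manhattan(dt, "PHAZ_CD4_D_pooled", "manhattan.png")
snapshot_3d(dt, region_query(chrom = "chr2", start = 204e6, end = 204.2e6),
            polarized = TRUE, ptable = pt, out_path = "region3d.png")
trax_report(gm, coh, dt, "rs1000013", "rs1000013.html")
export_region_json(dt, region_query(snp_id = "rs1000013", flank_bp = 5e4),
                   out_path = "region.json")
```

The same workflow is available from a shell via the bundled CLI
(`inst/exec/gwascan`): `simulate`, `qc`, `battery`, `polarize`,
`density`, `tophits`, `trax`, `snapshot`, `manhattan`,
`export-region`; every run writes a JSON manifest with input hashes for
reproducibility.

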