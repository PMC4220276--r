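---
title: "Multi-test association screens: models, polarization and density scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-test association screens: models, polarization and density scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwascan)
```

# The object of study

`gwascan` computes and post-processes a **Data Table**: a SNP × test
grid where every cell carries a p-value and a Quantitative Association
Statistic (QAS). The QAS is a positive effect measure with 1.0 as the
null, oriented by the *minor* allele: QAS > 1 means the minor allele is
associated with the adverse outcome ("susceptible"), QAS < 1 with
protection ("resistant"). Three QAS kinds are used, matching the design
of each test:

* **odds ratio** for 2×2 contingency designs, the cross-product
  `ad/bc` with a Haldane–Anscombe 0.5 correction applied to every cell
  when any cell is zero;
* **relative hazard** (hazard ratio) for survival designs, the
  exponentiated Cox regression coefficient;
* **ez2-transformed correlation** `(1 + r)/(1 − r) = exp(2 atanh r)`
  for categorical designs larger than 2×2, where `r` is the
  ordinal-by-ordinal correlation of genotype class and outcome class.
  This maps r = 0 to 1, is monotone, and satisfies
  `ez2(−r) = 1/ez2(r)`, so inversion of direction is exactly the
  reciprocal on the QAS scale — the property the polarization layer
  relies on.

# The test battery

A battery is a list of rows, each crossing a test family with its
axes: clinical endpoints × genetic models × serostatus contrasts ×
breakpoint schemes × cohort subsets. Eleven families are implemented,
organized by disease stage:

| Stage | Families | Engine |
|---|---|---|
| I Infection | INF | contingency (genotype or allele × serostatus contrast) |
| II Progression | PDCA2, PDCAM, PHAZ | CTSD contingency; Cox PH |
| III Sequelae | SEQCA, SEQC1, SEQSA, SEQS1 | contingency (SC+SP); Cox PH (SC only) |
| IV Treatment | HRTC, HRTS | contingency; Cox PH on HAART endpoints |
| QC | HWE | exact-conditional Hardy–Weinberg |

**Genetic models.** Dominant (D: carrier of ≥1 minor allele),
recessive (R: homozygous minor), codominant (CD: three ordered
classes), allelic (A: each sample contributes its two alleles; defined
for infection tests only). D and R coding sum to the CD code, a
consistency the tests exploit.

**Infection tests** compare seroconverters (SC) against uninfected
strata in three contrasts: SC vs HREU, SC vs HREU+OSN, and the
three-class SC vs HREU vs OSN (ordinal HREU < OSN < SC, ordered by
exposure-adjusted infection propensity). Seroprevalent (SP) samples
entered the study infected and carry no information about acquisition,
so they are always excluded here.

**CTSD classification** (categorical tests for survival data) turns a
right-censored endpoint into classes at configured breakpoints. The
removal rules matter: subjects censored before the (last) breakpoint
cannot be classified and are removed; SP subjects failing before the
first breakpoint are removed because their baseline is the first study
visit rather than seroconversion, making early failure times
incomparable; everyone else failing or censored after the last
breakpoint forms the long-term-survivor class. In the multipoint form,
failures are binned by the breakpoint interval they fall into, ordered
so that a larger class code means faster progression (this orients the
correlation-based QAS). The dichotomous default breakpoint is 7 years;
the multipoint default is (3, 7, 11) — conventional AIDS-progression
horizons, and fully configurable per battery row since real analyses
tune them per endpoint.

**Categorical engine.** Chi-square without continuity correction;
when any expected cell falls below 5, an exact Fisher test (enlarged
workspace; deterministic — no Monte-Carlo p-values, so identical
inputs always give byte-identical Data Tables). A codominant exposure
against a dichotomous outcome uses the Cochran–Armitage trend test with
scores 0/1/2, the standard choice for a 3×2 genotype table.

**Survival engine.** Cox proportional hazards of the endpoint on the
coded genotype (binary for D/R, 0/1/2 trend for CD), p from the
likelihood-ratio test, QAS = fitted hazard ratio. Cells with no
events, a monomorphic exposure, or a failed fit are recorded as
missing with a reason code, never as numbers. Coefficients beyond
|β| > 10 flag the cell for a penalized-likelihood (Firth-type) re-fit
by the user; the engine itself does not silently change estimator.

**Missingness policy.** Genotype and clinical missingness is handled
per test (pairwise deletion): a sample missing one endpoint still
contributes to every other test. This mirrors how per-test patient
counts differ across a real battery.

**Multiple testing.** Deliberately, no genome-wide correction is
applied inside the engine: the point of the unabridged table is to
surface sub-threshold candidates for replication. Bonferroni/FDR
annotation belongs at the reporting layer.

# Hardy–Weinberg QC

The HWE test is exact-conditional for samples under 1000 (enumerating
heterozygote counts given the allele counts) and chi-square above. The
**mid-p** variant is the default: the plain exact test is conservative
at typical GWAS panel sizes — at n = 200 and MAF 0.3 its measured
type-I error is ≈ 0.044 at α = 0.05, below the 99% Monte-Carlo band,
while mid-p sits at ≈ 0.053, inside it. Monomorphic sites return p = 1
with a flag. QC filters apply in a fixed order — sample call rate
(≥ 0.90), SNP call rate (≥ 0.95), MAF (≥ 0.01), HWE (p ≥ 1e−6) — each
on the survivors of the previous step; the defaults follow GWAS
convention and are configurable. Filtering is idempotent.

# Signed D′ and polarization

For an index SNP, signed D′ is computed against up to 80 SNPs on each
side (windows truncate at chromosome ends). Haplotype frequencies come
from unphased genotypes: all two-locus genotype classes except the
double heterozygote resolve to known haplotype counts; the double
heterozygotes are split between coupling and repulsion phases by EM.
Numerical care was needed in three places, found by testing against a
brute-force grid-search likelihood oracle:

1. the likelihood in the haplotype frequency `p11` can be bimodal
   (coupling vs repulsion phase), so the EM runs from three starts —
   linkage equilibrium and near both feasibility boundaries — and the
   highest-likelihood solution wins;
2. EM converges sublinearly when the optimum lies on a boundary
   (|D′| = 1), so the 1-D profile is polished with a bounded optimizer
   and the boundaries themselves are always candidates;
3. locus order is canonicalized before the computation so that
   `dprime(a, b)` equals `dprime(b, a)` to the bit (the quantity is
   symmetric; floating-point summation order is not).

After these, the worst disagreement with the oracle over hundreds of
random n = 50 fixtures is below 1e−5. D = p11 − pA·pB is normalized by
`min(pA(1−pB), (1−pA)pB)` for D ≥ 0 and `min(pA·pB, (1−pA)(1−pB))`
otherwise.

Marks follow fixed thresholds: 1 for D′ > 0.9, −1 for D′ < −0.9, 0
otherwise; the index SNP gets 1; monomorphic or undefined neighbours
get 0. Polarization replaces QAS by 1/QAS at mark −1 rows only —
p-values never change, mark 0 rows are displayed untouched (the
conservative reading: weak LD gives no license to reorient a result),
and applying the same polarization twice is the identity. Because a
relabeling of which allele is minor at a neighbour flips both its D′
sign and its raw QAS direction, the *polarized* QAS is invariant to
allele labeling — a property test in the suite.

# Density and top hits

Density is computed per SNP in two steps: (1) for each test, the mean
of −log10 p over the window centred at the SNP (its own cell included;
missing cells skipped, not zero-filled — zero-filling would bias
regions with dense missingness); (2) the per-test means aggregated by
mean or max, over all tests or over one disease stage's tests. Windows
are counted in SNPs or in Kbp per side and truncate at chromosome
ends. Base-10 logs are used throughout (the Manhattan-plot
convention). With the window spanning the whole region, density
reduces exactly to the global mean — a limit the tests check, along
with equivalence to a brute-force double-loop oracle at 1e−12.

Top hits rank SNPs by max −log10 p, by max |log QAS| (so protective
and susceptible effects rank symmetrically), or by density; ties break
deterministically by (chrom, pos).

# Reports

The machine-testable contract of every visual artifact is its sidecar
(TSV or JSON), not the pixels: snapshot cell grids list the exact
p-bin, hue and height per cell; TRAX sidecars print p and QAS at full
double precision and must equal the Data Table cells exactly; KM
curves are the product-limit estimates from `survival::survfit`,
stratified by the three genotypes. The color scale maps p > 0.05 to
neutral grey and deeper bins — default edges (0.05, 1e−2, 1e−3, 1e−4,
1e−5, 1e−8), only the first of which is fixed by the display
convention — to richer colors; hue encodes QAS side (green < 1 <
red), and intensity is `min(1, |log10 QAS| / log10 cap)` with cap 10,
a simple saturating ramp chosen because the display convention fixes
only "intensity reflects the QAS".

# The synthetic cohort

`simulate_genotypes()` draws haplotypes per LD block by a copying
process: a block-wide ancestral frequency, then each SNP copies its
left neighbour with probability equal to the block's D′ target. For a
stationary chain the adjacent-pair D′ equals the target in
expectation and decays with distance — enough LD realism for testing
windowed statistics, while real human LD maps, recombination hotspots
and demography are deliberately out of scope.
`simulate_tagged_region()` builds the canonical polarization test-bed:
one causal variant whose minor allele is tagged by proxies in coupling
(D′ = +1) or repulsion (D′ = −1), with thinned tag frequencies so
proxies vary in power (repulsion tag frequencies are scaled so
minor-allele anchoring cannot silently flip them back to coupling).

`simulate_cohort()` assigns risk groups from a configurable mix
(default 10% HREU, 10% OSN, 50% SC, 30% SP — a follow-up-cohort-like
composition), draws infection status from a logistic model with the
planted odds ratio, and event times from exponential
proportional-hazards models (baseline 0.08/year, configurable) with
independent exponential censoring (0.05/year). Exponential baselines
were chosen over Weibull because they admit closed-form oracles;
proportionality is then exact, which is precisely what a
parameter-recovery test needs. One sequela per affected sample is
flagged `was_first` (the earliest). What passing tests on these data
do *not* show: robustness to non-proportional hazards, informative
censoring, population stratification (the engine expects
structure-corrected inputs), or call-rate artifacts correlated with
phenotype.

# Problem sizes used in the checks

The automated checks run at the sizes their claims are about: battery
enumeration (123/144/60/327) is exact and instant; the polarization
concordance study uses 100 replicates of an 80-proxy region at
n = 2,000 and hazard ratio 2.5; null calibration uses 10,000
simulations per family (n = 500 for the contingency tests, n = 200
genotype draws for HWE); hazard-ratio recovery uses 200 replicates at
n = 2,000; oracle equivalence uses 50 × 10 tables and n = 50 LD
fixtures; the end-to-end discovery property embeds a 41-SNP causal
region in 80 null SNPs and runs 50 replicates.

# Known limitations

* Single-SNP exposures only; no covariate adjustment inside the Cox
  fits and no meta-analysis across groups.
* The ez2 QAS for >2×2 designs treats both margins as ordinal; for the
  three-class infection contrast the HREU < OSN ordering is a modeling
  choice.
* The exact CTSD test statistic is implemented as the chi-square /
  trend contingency machinery on the classified table; other
  elaborations of "categorical tests for survival data" exist.
* Gene-name region queries require a user-supplied BED file; no genome
  annotation is bundled.
* The 3D snapshot is a static shaded-tile render; the interactive
  browser experience is out of scope, with the JSON region export as
  the integration point for any front-end.
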