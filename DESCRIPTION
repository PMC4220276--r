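Package: gwascan
Title: Multi-Test GWAS Association Tables with LD Polarization, Density
    Scoring and Per-SNP Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline engine for multi-test genome-wide association
    screens on longitudinal cohorts. Builds a SNP-by-test Data Table of
    p-values and Quantitative Association Statistics (odds ratios, relative
    hazards, or transformed correlations, all centred at 1) from genotype
    and clinical data, running a configurable battery of categorical,
    survival (Cox proportional hazards), categorical-tests-for-survival-data
    and Hardy-Weinberg tests under dominant, recessive, codominant and
    allelic genetic models. A discovery layer polarizes effect directions
    across linkage-disequilibrium neighbourhoods via signed D', scores
    regions by windowed density of -log10 p, and ranks top hits. Renders
    Manhattan plots, 2D heat and 3D checkerboard region snapshots, per-SNP
    TRAX report documents with contingency bar plots and Kaplan-Meier
    curves, and a versioned JSON region export. Includes a synthetic-data
    module simulating LD-blocked diploid genotypes and HIV-like cohorts
    with planted allelic effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
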