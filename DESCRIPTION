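Package: asepower
Title: Allele-Specific Expression Versus Genotypic eQTL Mapping of
    cis-Regulatory SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis machinery for comparing the statistical
    power of allele-specific expression (ASE) analysis with genotypic
    total-expression (GTE, i.e. cis-eQTL) mapping for detecting cis-acting
    regulatory SNPs. Provides a synthetic cohort generator with known ground
    truth (Hardy-Weinberg phased genotypes, two-channel allele intensity
    signals with a quadratic dye bias, allelic-imbalance and additive
    expression effects, age/sex confounders), quantification of signed ASE
    levels from two-channel signals with phase orientation and transcript
    aggregation, phase-aware ASE regression and covariate-adjusted dosage
    regression over cis windows with group-size filters, Bonferroni and
    Benjamini-Hochberg multiple-testing control, permutation-based null
    calibration, and power-comparison reports (significance counting under
    down-sampling, top-list overlap, MAF-binned detection curves and
    TSS/TTS positional enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
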