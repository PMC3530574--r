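# asepower

Power comparison of two designs for mapping *cis*-regulatory SNPs
(cis-rSNPs) from cohort genotype + expression data:

* **ASE analysis** — allele-specific expression: the imbalance between a
  transcript's two alleles, measured *within* each heterozygous sample as
  the difference of cDNA and gDNA allele fractions at phased heterozygous
  SNPs, `A1c/(A1c+A2c) − A1g/(A1g+A2g)`, oriented to each sample's
  haplotype 1 and averaged over the transcript body.
* **GTE mapping** — genotypic total expression, i.e. classical cis-eQTL
  analysis: total expression regressed *between* samples on minor-allele
  dosage (0/1/2) with age and sex as confounders.

Because ASE cancels trans-acting and environmental variation within each
sample, it detects the same cis effects with far fewer samples. The
package provides everything needed to quantify that advantage on synthetic
cohorts with known ground truth: a cohort generator (phased Hardy–Weinberg
genotypes, two-channel allele signals with a quadratic dye bias, matched
allelic-imbalance and additive-expression effects, age/sex confounders,
missing calls, switch errors), the full ASE quantification path
(normalization, phase orientation, transcript aggregation, region-SD QC),
both association scans over 100 kb/500 kb cis windows with the group-size
filters (≥4 ASE / ≥3 GTE values per non-empty genotype group), Bonferroni
and Benjamini–Hochberg step-up correction, permutation-based null
calibration, and the standard power instruments (significance counting
under down-sampling, top-list overlap, 1% MAF-bin detection curves,
TSS/TTS positional enrichment).

The ASE test is phase-aware: heterozygotes form two groups by which
haplotype carries the minor allele (coded +1/−1), homozygotes are the
baseline (0), and the ASE level is regressed on this code through the
origin — a form that is exactly invariant to each sample's arbitrary
haplotype labelling. See the methods vignette
(`vignettes/ase-power-mapping.Rmd`) for the model, the generator's scope
and the numerical conventions.

## Worked example

```r
library(asepower)

co  <- simulate_cohort(sim_config(n_samples = 100, n_transcripts = 50, seed = 7))
co
#> ase_cohort: 100 samples, 900 SNPs, 50 transcripts (29 causal)

ase <- quantify_ase(co)
ase
#> transcript_ase: 50/50 transcripts kept (>= 5 informative SNPs), 100 samples, mean aggregation

scan_ase <- adjust_scan(run_scan(co, "ase", ase = ase))   # m = 803 retained tests
scan_gte <- adjust_scan(run_scan(co, "gte"))              # m = 746 retained tests

count_significant(scan_ase, "bonferroni", 0.05)$snps
#> [1] 27
count_significant(scan_gte, "bonferroni", 0.05)$snps
#> [1] 15

head(scan_ase[order(scan_ase$p), c("transcript","snp","maf","slope","p","p_bonf")], 3)
#>  transcript      snp   maf slope        p   p_bonf
#>      tx0015 snp00268 0.404 0.211 1.54e-45 1.23e-42
#>      tx0004 snp00064 0.403 0.198 2.89e-41 2.32e-38
#>      tx0032 snp00567 0.372 0.200 1.53e-40 1.23e-37
```

Of the 29 transcripts given a causal cis-rSNP (true allelic shift 0.2,
matched additive expression shift 0.6), the ASE scan recovers 27 unique
SNPs at Bonferroni 0.05 versus 15 for GTE at the same n — and the three
strongest ASE hits above are exactly the simulated causal SNPs of their
transcripts, with slopes ≈ 0.2 recovering the injected allelic shift.

`run_pipeline(config, out_dir)` runs the whole chain
(simulate → quantify → scan ×2 → correct → permute → power) from a YAML
config and writes VCF/BED/TSV/JSON artifacts with provenance headers;
`inst/scripts/run_pipeline.R` wraps it for the shell.

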