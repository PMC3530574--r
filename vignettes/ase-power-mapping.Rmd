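---
title: "Mapping cis-regulatory SNPs: allele-specific expression versus eQTL power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis-regulatory SNPs: allele-specific expression versus eQTL power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most trait-associated SNPs fall outside protein-coding sequence, and the
usual first step toward a function is to ask whether a SNP correlates with
the expression of a nearby gene. Two designs answer that question from the
same raw material (genotypes plus expression measurements in a cohort):

* **GTE mapping** (genotypic total expression, i.e. cis-eQTL analysis)
  regresses *between-sample* differences in total expression on genotype
  dosage. Every source of between-sample variation — trans-acting factors,
  environment, batch — sits in the residual.
* **ASE analysis** (allele-specific expression) compares the expression of
  a transcript's two alleles *within* each heterozygous sample. Both alleles
  share the same cellular environment, so trans and environmental variation
  cancel, leaving a far cleaner readout of a cis effect.

`asepower` implements both scans end to end, together with a synthetic
cohort generator with known ground truth, so that the claim "ASE needs far
fewer samples than eQTL mapping for the same cis-signals" can be exercised,
calibrated and stress-tested without access to controlled human data.

## The measurement model

The quantification path mirrors a two-colour genotyping-array design in
which genomic DNA (gDNA) and cDNA of each sample are assayed on the same
array. For a heterozygous SNP the two allele channels give an allele
fraction, and the per-SNP ASE level is

$$\mathrm{ASE} =
\frac{A_{1,\mathrm{cDNA}}}{A_{1,\mathrm{cDNA}} + A_{2,\mathrm{cDNA}}}
- \frac{A_{1,\mathrm{gDNA}}}{A_{1,\mathrm{gDNA}} + A_{2,\mathrm{gDNA}}},$$

the gDNA fraction acting as the per-SNP reference for what "balanced"
looks like on that assay. Observations with zero total signal are missing
data — never 0 or 0.5 — because fabricating balance would bias every
aggregate downstream.

Raw two-colour fluorescence carries an intensity-dependent dye bias.
`normalize_fractions()` fits, per sample array, a least-squares quadratic
of the heterozygous gDNA fraction's deviation from 0.5 against
$t = \log_{10}(\text{total signal})$ and subtracts the fitted curve from
every fraction (gDNA and cDNA) on that array. Heterozygous gDNA is the only
internal standard whose truth (0.5) is known, which is why the fit uses it
alone; arrays with fewer than 30 usable hets are passed through unchanged
with a warning rather than fitted on noise.

Within a sample, per-SNP levels are signed quantities: which allele is
"allele 1" is arbitrary per SNP. Haplotype phase turns them into one
coherent signal: each level is oriented so that positive always means
"haplotype 1 over-expressed" in that sample, then averaged over the
heterozygous SNPs inside the transcript body (`quantify_ase()`). A SNP is
*informative* if at least one cohort sample is heterozygous; transcripts
with fewer than five informative body SNPs are dropped (a relaxed threshold
of three is available as `min_informative = 3`). The aggregator is the
arithmetic mean by default with a `median` switch — descriptions of this
design vary between the two and the choice is deliberately exposed rather
than hidden.

ASE-measuring SNPs are restricted to the transcript body (TSS to TTS):
cDNA signal requires transcription, and the generator reflects this by
emitting zero cDNA signal for flank SNPs. Flank SNPs still serve as *test*
SNPs in the association scans.

## The two association scans

Both scans test every genotyped SNP within a cis window — the transcript
body plus 100 kb on each side by default, 500 kb as the wide variant —
against the transcript's phenotype.

**ASE scan.** At a test SNP, heterozygous samples split into two groups by
phase: minor allele on haplotype 1 (coded $+1$) or on haplotype 2
($-1$); homozygotes form the baseline group ($0$). The transcript ASE level
(oriented to haplotype 1) is regressed on this coded covariate *through the
origin*, with a two-sided t-test on the slope. The zero-intercept model is
a deliberate choice: each sample's haplotype labels are arbitrary, and
relabelling a sample flips its covariate and its oriented ASE level
jointly. A through-origin slope ($\sum x_i y_i / \sum x_i^2$) is exactly
invariant under every such relabelling, while an intercept would estimate a
label-dependent and therefore meaningless quantity. It also encodes the
biology literally: homozygotes sit at covariate 0 with expected ASE 0.
(The group-size *filter* below is the one place label-dependence remains:
a flip moves a sample between the $+1$ and $-1$ groups and can admit or
drop a borderline test, though never change a computed p-value.)

**GTE scan.** Total expression is regressed on minor-allele dosage
(0/1/2) with age and sex as confounders; two-sided t-test on the dosage
slope. A covariate with no variance in the analyzed subset (a single-sex
draw, say) is dropped with a warning instead of producing a singular fit.

**Group-size filters.** A test is performed only if every *non-empty*
genotype group carries at least 4 values (ASE) or 3 values (GTE), and at
least two groups are present. Requiring only non-empty groups — rather
than all three — keeps low-MAF SNPs testable when the rare homozygote
class is simply absent; a `require_all_groups` switch implements the
stricter reading. These filters are not cosmetic: the permutation analysis
below shows that without them the small-p tail of the null is inflated by
tests resting on one or two observations.

**Multiple testing.** `bonferroni_adjust()` implements
$p_\mathrm{corr} = p \cdot m$ and `bh_adjust()` the Benjamini–Hochberg
linear step-up $(m/i)\,p_{(i)}$ with the monotonicity fix (each adjusted
value replaced by the smallest value at any higher rank). Both are written
out in full because they are part of the method under study, and both are
cross-checked in the test suite against `stats::p.adjust` as an independent
reference. The denominator $m$ is always the post-filter count of retained
tests and is recorded in every output. At genome scale the arithmetic gives
the familiar cutoffs: $0.05/638845 \approx 7.8\times10^{-8}$ and
$0.05/428000 \approx 1.2\times10^{-7}$.

## What the generator simulates — and what it does not

`simulate_cohort()` draws, per transcript, body SNPs and flank SNPs with
per-SNP MAF uniform on `maf_range` (default 0.01–0.5, emulating a
genome-wide genotyping panel's spectrum), phased Hardy–Weinberg genotypes,
and, for a `causal_fraction` of transcripts, one causal SNP uniformly
placed over the cis window. In a sample heterozygous at the causal SNP, the
haplotype carrying the minor allele is over-expressed: every heterozygous
body SNP's cDNA fraction shifts by `ase_effect` toward the allele on that
haplotype. Total expression gains `gte_effect` per minor allele. Noise
levels default to the observed scales of the assay this design emulates:
gDNA allele-ratio SD 0.014 and per-SNP RNA allele-ratio SD 0.10 within a
region (modelled per SNP because that is the quantity the region SD
measures within a sample). A quadratic dye bias (default coefficients
0.03, −0.01, 0.002 over $t \in [2, 4]$) distorts all emitted fractions so
the normalization step has real work to do, age (uniform 18–65) and sex
(Bernoulli 0.5) shift expression, genotypes go missing MCAR at 2%, and
`introduce_phasing_errors()` flips heterozygote phase at a configurable
switch-error rate.

Matched default effects: `ase_effect = 0.2` corresponds to one haplotype
expressed at $0.7/0.3 \approx 2.3$ times the other, i.e.
$\log_2 2.33 \approx 1.2$ across the two alleles, so the additive default
`gte_effect = 0.6` per allele (on the unit-noise normalized expression
scale) represents the *same* regulatory effect seen through the
total-expression lens. Expression is generated directly on a normalized
scale with unit Gaussian noise, standing in for the variance-stabilized,
quantile-normalized arrays such cohorts use; array-level normalization is
out of scope and orthogonal to the power comparison.

Deliberately not simulated: LD between SNPs (only the causal site carries
signal — the comparison is between methods, not between tagging
structures), population structure, alternative splicing, and read-count
(RNA-seq) noise. Passing tests therefore demonstrate correctness of the
machinery and the direction of the power difference under clean cis
signals; they do not certify behaviour under LD-driven association
spreading or splice-variant interference, which the region-SD QC
(`region_sd_qc()`) can only flag, not model.

## Calibration and the power comparison

`null_calibration()` shuffles sample identifiers on the genotype/phase
side only — phenotype matrices are never recomputed, an invariant the code
asserts — and pools post-filter p-values across permutations. On a
global-null cohort (n = 100, 200 transcripts, 100 permutations, ~3 × 10⁵
pooled tests) the filtered null is uniform: fraction below 0.05 within
[0.04, 0.06] and a Kolmogorov–Smirnov test comfortably above the 0.01
level. Removing the filters reproduces the rationale for them: tests whose
smallest non-empty group holds fewer than 4 values — overwhelmingly
low-MAF SNPs — show roughly twice the nominal rate of p < 10⁻³. The
mechanism in the generator is heteroscedasticity: a sample's transcript
ASE averages over its heterozygous body SNPs, so samples with one usable
SNP are noisier, and a t-test resting on one or two such samples is
anticonservative in the far tail.

The power instruments mirror the three standard comparisons:
`downsample_counts()`/`power_table()` count significant associations,
unique SNPs (best association per SNP, p-ties broken by transcript id) and
transcripts at FDR 5%/1% and Bonferroni 0.05/0.01 across random sample
subsets (medians over runs); `toplist_overlap()` compares equal-size
top-SNP lists within the SNPs eligible for both methods, with the GTE list
size as denominator; `maf_power_curve()` bins detections into 1% MAF bins
(half-open, MAF = 0.5 in the last bin) with a centred 5-bin sliding
average truncated at the edges; `positional_enrichment()` profiles
detection fractions in 1 kb bins of strand-oriented distance to TSS and
TTS (upstream negative).

At the desk scale used in the tests and the acceptance script (500
transcripts, half causal, matched effects, n ∈ {188, 95, 50}, three
down-sampling runs at the reduced sizes), the ASE scan finds more
Bonferroni-significant unique SNPs than the GTE scan at every n, and the
ASE/GTE ratio grows as the cohort shrinks — the qualitative signature of
the within-sample design's power advantage. Absolute counts at this scale
are not comparable to a genome-wide cohort's; the direction and the
monotone trend are the reproducible content.

## Numerical conventions and edge cases

* Internal coordinates are 0-based, transcript intervals half-open
  (BED-style); VCF positions are 1-based and converted at the boundary.
* Cis windows are closed intervals on SNP positions and clipped at
  chromosome start.
* Zero-total-signal observations, missing genotypes and unphased
  heterozygotes are excluded, never imputed.
* A test with zero response variance yields a record with missing p and a
  `degenerate` flag rather than silently disappearing.
* BH ties: tied p-values receive identical adjusted values via the
  running-minimum pass over a stable sort.
* TSV floats are written with 12 significant digits so write-then-read
  round-trips at working precision; association TSVs carry `#` provenance
  headers recording the retained test count `m` and the seed.
* All randomness flows from a single integer seed per entry point;
  identical configuration and seed give byte-identical artifacts.

## Known limitations

The generator's single-causal-SNP-per-transcript world makes "unique
significant SNPs" nearly synonymous with "detected causal SNPs"; in real
data LD spreads each signal over many SNPs and the counting instruments
measure a mixture of power and LD structure. The ASE noise model is
Gaussian on the fraction scale, which is adequate away from fraction 0/1
but optimistic for extreme imbalance. And the comparison inherits the
design's premise that the same SNP set is tested by both methods; platform
differences between genotyping and expression assays are reduced to a
genotype-concordance check (`genotype_concordance()`).
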