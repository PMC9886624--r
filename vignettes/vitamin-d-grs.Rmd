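---
title: "Methods: a six-variant vitamin D risk score and its supplementation-stratified analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a six-variant vitamin D risk score and its supplementation-stratified analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdgrs)
```

## The model

Serum 25-hydroxyvitamin D (vitamin D status) is partly heritable. A small
number of common variants at well-replicated loci — *GC*, *DHCR7*,
*CYP2R1*, *CYP24A1*, *AMDHD1*, *SEC23A* — carry per-allele effects on the
Z-score scale of circulating 25(OH)D. The package's score is the standard
weighted allele count

$$\mathrm{GRS}_i \;=\; \sum_{j=1}^{m} X_{ij}\,\beta_j , \qquad m = 6,$$

where $X_{ij} \in [0, 2]$ is individual $i$'s dosage of variant $j$'s
effect allele and $\beta_j$ the GWAS-derived per-allele effect. Two panel
weights are negative (*SEC23A* rs8018720, *GC* rs2282679);
`flip_negative_weights()` re-expresses those entries on the non-effect
allele so all weights are positive. Because $X' = 2 - X$, the flipped raw
score equals the original plus the constant $2\sum |\beta_{\text{neg}}|$,
so Z-scored results are identical — a property the test suite asserts to
$10^{-12}$.

The score enters analyses Z-scored within the scored cohort ("per 1 SD of
GRS"), and vitamin D enters Z-scored cohort-wide. Strata reuse whole-cohort
Z-scores rather than re-standardizing, which keeps stratum estimates on a
common scale; this is the most natural reading of "per-SD" effects reported
for a whole cohort and is the package's fixed convention.

## Allele harmonization and proxies

Weight tables state an effect/other allele pair; genotype files state
REF/ALT on an arbitrary strand. `harmonize_alleles()` resolves the
orientation in the conventional order: direct match (effect = ALT, or
effect = REF with dosage transform $2 - x$), then reverse-complement
(strand-flip) match. A weight whose two alleles are complementary (A/T or
C/G) is *palindromic*: a strand flip is undetectable from alleles alone, so
such weights are refused unless the rsid is explicitly whitelisted. The
packaged configuration whitelists rs8018720 (C/G) because the panel is
designed for assay-based genotyping where strand is known by design; this
is a deliberate, documented default, and the safe behaviour (refusal) is
what any non-whitelisted palindromic variant gets. Anything else is a
`mismatch` and is an error, never silently dropped at scoring time.

Two panel variants have documented proxies in near-complete LD:
rs6538691 substitutes for rs10745742 ($R^2 > 0.99$, T alleles
corresponding) and rs2282679 is the genotyped stand-in for rs3755967
($R^2 = 0.9719$, correlated alleles C=T, T=G). `resolve_proxy()` re-keys a
weight to its proxy only when the target is absent, translating alleles
through the stated bijection and never altering the weight itself. LD is
taken as given; the package computes no LD of its own (no reference panel
is in scope), so the recorded $R^2$ is informational.

## Quality control

`variant_qc()` applies the conventional biobank-scale filters, all
overridable but defaulting to: minor allele frequency $\ge 0.01$,
Hardy–Weinberg equilibrium $p \ge 10^{-5}$, call rate $\ge 0.90$, and
imputation info score $\ge 0.3$ when one is recorded. MAF is computed from
mean dosage / 2 and folded to $\le 0.5$, making it invariant under allele
relabelling. The HWE test is the 1-df chi-square goodness of fit of
observed genotype counts against $np^2, 2npq, nq^2$ at the sample allele
frequency — the conventional default at large sample sizes and exactly
checkable by hand; fractional (imputed) dosages skip it, which the QC
report records. `sample_qc()` removes samples missing more than 10% of the
panel. Genetic ancestry is accepted as an optional sample label for
exclusion, never inferred: six SNPs carry no usable ancestry information.

Missing dosages at scoring time follow a selectable policy:
mean imputation with $2\hat p_j$ (the default, matching common scoring
tools), per-sample exclusion of the missing variant, or dropping the
sample. The choice is reported per sample (`n_imputed`,
`n_variants_used`). Samples missing the whole panel are flagged absent.

## Association analysis

All models are ordinary least squares on complete cases, with the
exclusion count logged. The predictor screen fits one age- and
sex-adjusted model per candidate and corrects the candidate p-values
across the screened set with the Benjamini–Hochberg step-up procedure
(FDR < 5% flags). Supplementation dose enters the screen as
$\log(\text{dose} + 1)$ among supplementers only — dose is undefined off
supplement — while the multivariable models use the binary supplementation
indicator.

The main models are:

* full cohort: `vd_z ~ grs_z + age + sex + bmi + supplementing + ms_status`;
* within each supplementation stratum: `vd_z ~ grs_z + age + sex + bmi
  (+ ms_status)`, keeping MS status as a covariate whenever it varies in
  the stratum (constant columns are dropped rather than left to produce a
  singular design).

`adjusted_r2_delta()` compares the covariate-only model with the same
model plus the score using the $(n-1)/(n-p-1)$ adjustment. Case/control
genotype distributions are compared per variant with Pearson's chi-square
on the $2 \times 3$ table (no continuity correction), collapsing genotype
classes absent from both groups.

## The synthetic cohort generator

No public genotype–phenotype data exist for the cohorts this design
targets, so `simulate_cohort()` generates cohorts with the statistical
structure the analysis assumes, and every pipeline stage is exercised on
that output (the simulator writes VCF + TSV that the scoring stage reads
back).

**Genotypes** are independent Binomial(2, $p_j$) draws — Hardy–Weinberg at
each locus, linkage equilibrium across loci. The defaults
(`default_allele_freqs()`: 0.40, 0.75, 0.40, 0.79, 0.82, 0.72 for
rs10745742, rs12785878, rs10741657, rs17216707, rs8018720, rs2282679) are
approximate European-ancestry effect-allele frequencies from public
reference ranges; they are the generator's fixed defaults, not estimates
from any particular cohort. Real panels have LD structure, genotyping
error, and ancestry stratification that this generator deliberately does
not emulate — passing tests therefore validate the pipeline's arithmetic
and inference under the stated model, not robustness to those artefacts.

**Behaviour and covariates.** Supplementation is Bernoulli with
MS-status-specific prevalence (defaults 71.1% MS, 26.7% control for the
study preset; 5.1% for the biobank preset). Dose among supplementers is
log-normal parameterized by its median ($\text{median} = e^{\mu}$;
defaults 1200 IU/day MS, 571 IU/day control, `dose_log_sd = 0.5`) —
doses are positive and right-skewed, and a median-parameterized log-normal
is the simplest distribution consistent with that. BMI is N(27, 4.5²)
kg/m², age N(55, 12²) years (N(58, 9²) in the biobank preset), sex
Bernoulli (≈ 74–75% female in the study preset).

**Phenotype.** In *additive* mode every sample receives
$\text{genetic} + \delta \log(\text{dose}+1) S_i + \text{covariates} +
\varepsilon$. In *titration* mode supplementers instead receive
$\tau + a \cdot \text{genetic} + \varepsilon$ — they dose toward a target
level $\tau$, and $a \in [0,1]$ controls how much genetic signal survives
(0 = fully masked). Titration replaces the dose and covariate terms for
supplementers entirely: conditional on titrating to the target, dose no
longer predicts the achieved level. The two modes exist because a
supplementer-stratum null is compatible with both low power and genuine
masking; the generator lets either hypothesis be simulated rather than
asserting one. The phenotype is finally Z-scored cohort-wide, with a
purely cosmetic nmol/L back-transform (mean 50, SD 20) for file output.

The genetic term is the raw weighted score when `grs_effect_sd = NULL`.
When a per-SD effect is given, the raw score is standardized by its
analytic Hardy–Weinberg moments ($\mu = \sum 2p_j\beta_j$,
$\sigma^2 = \sum 2p_j(1-p_j)\beta_j^2$) and scaled, so the generative
truth is stated directly in the units every result is reported in (SD of
vitamin D per SD of score). This is what makes parameter-recovery checks
exact rather than indirect.

## Calibration of the presets

The biobank preset targets a phenotype of unit variance: residual SD is
$\sqrt{1 - \beta_g^2}$ and covariate effects are folded into the residual,
because the biobank-style validation regression is unadjusted and any
non-genetic structure is indistinguishable from noise there.

The study preset's free parameters were fixed once, by measurement over
200 seeded replicates (`scripts/calibrate_study_preset.R`), to the design
point the package is built to exhibit: covariate-only adjusted $R^2$
around 0.37, a small incremental $R^2$ from the score, a full-cohort
multivariable score coefficient near 0.1 SD per SD, a clearly significant
non-supplementer stratum and a null supplementer stratum. The frozen
defaults are `titration_target = 0.97`, `noise_sd = 0.6`,
`grs_effect_sd = 0.17`, `titration_genetic_attenuation = 0`, and covariate
effects $-0.03$ per kg/m² BMI, $+0.01$ per year age, $+0.05$ female, MS
direct effect 0 (MS influences vitamin D only through supplementation
behaviour in titration mode). At that point the measured values were a
coefficient of 0.102, base adjusted $R^2$ 0.372 and full 0.383. A note on
internal consistency: with a standardized coefficient pinned near 0.1, the
incremental $R^2$ is necessarily about $0.1^2 \approx 0.01$, so the
full-model $R^2$ sits near 0.38 — a coefficient of 0.1 and an $R^2$ jump
of a full 0.02 cannot hold simultaneously.

## Numerical and degenerate-input choices

* Z-scoring uses the sample (n−1) SD and refuses zero-variance input; a
  monomorphic cohort therefore fails scoring loudly.
* The HWE statistic skips expectation cells that are exactly zero
  (monomorphic variants have statistic 0, $p = 1$).
* The orientation transform $x \mapsto 2-x$ is an involution, asserted in
  tests.
* Chi-square genotype tests collapse empty genotype classes and return
  statistic 0 / $p = 1$ when only one class remains.
* QC is idempotent: re-filtering a filtered matrix removes nothing.
* All generation is driven by a single integer seed; identical
  config + seed give byte-identical output files.

## Problem sizes used in checks

The shipped checks use cohort sizes chosen to make Monte-Carlo error
small relative to the quantities asserted while remaining quick on a
desktop: biobank-scale recovery at $n = 50{,}000$ (and the 18,882
supplementer subset size), study-scale behaviour as the mean of 200
replicates of the default 547-sample cohort, and generator fidelity at
20,000 MS samples.

## Known limitations

* The analytic variance explained by this panel,
  $\sum_j 2p_j(1-p_j)\beta_j^2$, is bounded above by
  $\sum_j \beta_j^2 / 2 \approx 0.0057$ for these weights — about 0.46% at
  the default frequencies. Larger variance-explained figures quoted for
  these loci in the literature rest on multi-signal, conditional GWAS
  accounting rather than this single-SNP closed form, and are not
  reproducible from the six tabulated weights alone.
* Six variants cannot support ancestry inference, relatedness checks, or
  LD-aware operations; none are attempted.
* The generator's independence assumptions (loci independent of each
  other and of covariates; supplementation independent of genotype) are
  idealizations; real cohorts may violate any of them.
* Season of sampling is not modelled.
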