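# vdgrs

Genetic determinants of serum vitamin D are real but small; supplementation
behaviour is large and confounded with who chooses to supplement. `vdgrs`
is an R package for analysing exactly that tension. It builds the standard
six-variant weighted genetic risk score (GRS) for serum 25-hydroxyvitamin D
from genotype data, and tests how the score's association with measured
vitamin D changes between people who do and do not supplement — the
situation that arises in multiple-sclerosis cohorts, where most patients
supplement at substantial doses.

It is written for epidemiologists and statistical geneticists who need a
tested, reproducible implementation of:

* **Score construction** — `GRS_i = Σ_j X_ij β_j` over six GWAS loci
  (*AMDHD1* rs10745742, *DHCR7* rs12785878, *CYP2R1* rs10741657,
  *CYP24A1* rs17216707, *SEC23A* rs8018720, *GC* rs2282679), with the
  negative-weight entries re-expressed on the non-effect allele, allele
  harmonization against arbitrary VCF REF/ALT orientations (including
  strand flips and palindromic-SNP refusal/whitelisting), and proxy
  substitution through documented LD allele maps
  (rs6538691 ↔ rs10745742; rs2282679 ↔ rs3755967).
* **Variant and sample QC** — MAF ≥ 0.01, 1-df Hardy–Weinberg chi-square
  p ≥ 1e-5, call rate ≥ 90%, imputation info ≥ 0.3; sample missingness
  ≤ 10%.
* **Association analysis** — an age/sex-adjusted predictor screen with
  Benjamini–Hochberg FDR, multivariable and supplementation-stratified
  OLS models of Z-scored vitamin D, adjusted-R² comparison of nested
  models, and case/control genotype-distribution chi-square tests.
* **Cohort simulation** — Hardy–Weinberg genotypes plus a phenotype with
  configurable genetic, supplementation-dose, and covariate structure, in
  either an *additive* mode or a *titration* mode in which supplementers
  dose toward a target level that masks genetic effects. Presets emulate
  a large population biobank and a 315-case / 232-control MS study.

## Worked example

The pipeline runs end-to-end on its own synthetic output — simulate a
study-like cohort, write it as VCF + TSV, read it back, QC, score, and
model:

```r
library(vdgrs)
res <- run_pipeline(study_preset(seed = 2025), "demo_out")
res$models[res$models$term == "grs_z", c("stratum", "estimate", "se", "p", "n")]
#>             stratum estimate     se       p   n
#> 1               all  0.06597 0.0331 0.04690 547
#> 2     supplementers -0.00404 0.0432 0.92550 308
#> 3 non-supplementers  0.16753 0.0509 0.00115 239
sprintf("adjusted R2: base %.3f -> with GRS %.3f", res$r2$r2_base, res$r2$r2_full)
#> "adjusted R2: base 0.400 -> with GRS 0.404"
```

Reading the output: in this 547-sample titration-mode cohort the GRS
predicts vitamin D clearly among the 239 non-supplementers (0.17 SD per SD
of score, p ≈ 0.001) and not at all among the 308 supplementers
(p ≈ 0.93) — supplementation has overwritten the genetic signal, which is
the behaviour the titration generator encodes. The full-cohort
multivariable estimate (0.066 here; near 0.1 on average over replicates)
sits between the strata, and adding the score to the covariate model moves
adjusted R² only slightly, because six common variants carry little of the
phenotype's variance. The age/sex-adjusted screen on the same cohort ranks
supplementation, MS status and BMI as the strongest predictors (BH-FDR
q < 0.05).

A shell front end wraps the same stages:

```sh
Rscript inst/cli/vdgrs.R all --config config.yaml --out out_dir
Rscript inst/cli/vdgrs.R score --vcf genotypes.vcf --out out_dir
```

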