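# hemocog

Blood-cell indices and cognitive function: association screening,
Mendelian randomisation, longitudinal rates of change and pathway
enrichment, in one tested R package.

## The problem

Low haemoglobin and anaemia are observationally associated with poorer
cognition and with Alzheimer's disease, but observational associations
cannot tell cause from consequence. `hemocog` is for epidemiologists and
biostatisticians who want to run — and, just as importantly, *validate by
simulation* — the full inference chain that addresses this question:

1. **Association screen** — per blood measure (HGB, MCH, RDW, …) and
   cognitive test, a general linear model with correction for age, sex,
   education and assessment centre, technical residualisation of the blood
   counts, Benjamini–Hochberg correction across the whole grid, anaemia
   classification (NICE rule: HGB < 13 g/100 mL for males, < 12 for
   females, strict), and age/sex-matched case–control extraction.
2. **Mendelian randomisation** — using SNPs with known blood-index effects
   as instruments. Per SNP, the Wald ratio
   `beta_j = Gamma_j / gamma_j` (outcome effect over exposure effect, SE
   by the delta method); combined by inverse-variance weighting
   (`beta = sum(w_j beta_j) / sum(w_j)`, `w_j = 1/se_j^2`), the weighted
   median (robust while valid instruments hold > 50% of the weight) and
   MR-Egger (free intercept estimating directional pleiotropy). One- and
   two-sample designs, instrument filtering (info > 0.9, exclusion lists,
   excluded genomic regions), allele harmonisation with palindrome
   dropping, and per-SNP funnel diagnostics.
3. **Longitudinal rates** — per-subject OLS slope of each blood measure on
   age (`measure = b0 + b1 age + e`), Welch t and Kolmogorov–Smirnov group
   comparisons with FDR per test family, MMSE extremes splits and a
   continuous MMSE linear model.
4. **KS pathway enrichment** — per-gene linear-model t-statistics or
   permutation correlations against a subject-level trait, then a
   two-sample KS test of in-pathway versus out-of-pathway statistics per
   gene set (GMT input), BH-corrected.

Because the real cohorts behind such analyses are access-restricted, the
package includes a synthetic-cohort generator with known ground truth
(additive genotypes, a configurable causal effect, optional pleiotropy, a
shared confounder, covariates, longitudinal visits, pathway-structured
expression). Every estimator is validated against that truth; see the
methods vignette (`vignettes/blood-cognition-methods.Rmd`).

## Worked example

Simulate a biobank-style cohort (n = 20,000; 30 instrument SNPs; true
causal effect of MCH on reasoning = 0.05), estimate per-SNP associations
and run all three MR estimators:

```r
library(hemocog)

cfg    <- sim_config(n_individuals = 20000, m_snps = 30,
                     causal_beta = 0.05, seed = 1)
cohort <- simulate_cohort(cfg)
inst   <- estimate_snp_associations(cohort, "MCH", "reasoning")
run_mr(inst, n_boot = 1000, seed = 1)
#> Mendelian randomisation results
#> MR fit (ivw, 30 SNPs)
#>   beta = 0.0469 [0.0219, 0.0718], se = 0.0127, p = 0.000231
#> MR fit (weighted_median, 30 SNPs)
#>   beta = 0.0529 [0.0146, 0.0913], se = 0.0196, p = 0.00678
#> MR fit (egger, 30 SNPs)
#>   beta = 0.1332 [0.0314, 0.2349], se = 0.0519, p = 0.0103
#>   intercept = -0.0131 (se 0.0076), p = 0.0863
```

All three estimators recover the planted effect: the IVW and weighted
median CIs cover 0.05 tightly; Egger pays for its intercept with a wider
interval, and its intercept — the directional-pleiotropy estimate — is
compatible with the true value of 0 (p = 0.086). Compare the confounded
observational regression for the same cohort:

```r
fit_association(cohort, "MCH", "reasoning", age_min = 0)
#>   blood_measure   outcome      beta          se             p n_used
#> 1           MCH reasoning 0.1395298 0.006278315 4.090412e-108  20000
```

The observational beta (0.140) is nearly three times the true causal
effect (0.05) because exposure and outcome share a confounder — exactly
the gap MR is there to close.

The whole chain (simulate → screen → MR → rates → enrichment) runs from
one seeded configuration:

```r
res <- run_pipeline(demo_config(out_dir = "demo_run", seed = 1))
```

which writes the screen grid, per-method MR table, per-SNP diagnostics,
slope comparisons, enrichment results, a provenance record and a markdown
report into `demo_run/`, byte-identically for a fixed seed. A thin CLI
wrapper is at `inst/scripts/hemocog.R`.

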