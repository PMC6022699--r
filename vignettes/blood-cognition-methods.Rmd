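---
title: "Methods: blood-cell indices, cognition and Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-cell indices, cognition and Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocog)
```

# Scope

`hemocog` implements the inference chain used to ask whether red-blood-cell
indices (haemoglobin concentration HGB, mean corpuscular haemoglobin MCH,
red-cell distribution width RDW, and related complete-blood-count measures)
are causally upstream of cognitive performance:

1. a covariate-adjusted GLM **association screen** between blood measures
   and cognitive tests, with Benjamini–Hochberg correction;
2. **Mendelian randomisation** (MR) from per-SNP summary associations, with
   Wald ratio, inverse-variance weighted (IVW), weighted median and
   MR-Egger estimators plus pleiotropy diagnostics, in one- and two-sample
   designs;
3. **longitudinal rate-of-change** analysis: per-subject slopes of blood
   measures on age, compared between groups (disease case–control, MMSE
   extremes, MMSE as a continuous score);
4. distribution-based (Kolmogorov–Smirnov) **gene-set enrichment** from
   per-gene statistics.

Individual-level biobank data are access-restricted, so the package ships a
**synthetic-cohort generator** with known ground truth. Every stage is
validated by simulation against that truth; the generator is first-class,
tested code, not a fixture.

# The generative model

`sim_config()` encodes the structural model the analysis assumes. For
subject $i$ with dosages $g_{ij} \sim \mathrm{Bin}(2, f_j)$ at $m$
independent SNPs:

$$x_i = \textstyle\sum_j \gamma_j g_{ij} + \lambda_x c_i + \varepsilon_{x,i},
\qquad
y_i = \beta x_i + \textstyle\sum_j \alpha_j g_{ij} + \lambda_y c_i +
\mathbf{z}_i^\top \boldsymbol\eta + \varepsilon_{y,i},$$

where $x$ is the blood-index exposure, $y$ the cognitive outcome, $c$ a
latent scalar confounder, $\alpha_j$ optional direct (pleiotropic) SNP
effects and $\mathbf{z}$ the demographic covariates (age, sex, education,
assessment centre). A single linear confounder is the minimal structure
that makes MR non-trivially necessary: with $\beta = 0$ and
$\lambda_x \lambda_y \ne 0$ the observational regression of $y$ on $x$ is
biased away from zero while the true causal effect is null, and the tests
verify MR defeats exactly this construction. Linkage disequilibrium,
imputation noise beyond a constant info score, and population structure are
deliberately out of scope — the instruments model independent validated
loci.

## Default parameter scales

No published effect-size scale exists for the SNP-to-blood-index effects,
so the defaults are arbitrary but calibrated, once, to a realistic
biobank-like regime and then left alone:

* $\gamma_j$ spread over 0.08–0.20 exposure units per allele with effect
  allele frequencies in (0.1, 0.5). At $n = 20{,}000$ this puts every
  instrument's F-statistic far above the conventional weak-instrument
  threshold of 10 (roughly 50–300), so one-sample weak-instrument bias is
  negligible relative to the acceptance tolerances.
* Exposure noise 0.81 and confounder loadings 0.3/0.3 make the exposure
  variance close to 1, so $\gamma$ and $\beta$ read as standardised
  effects.
* Covariate effects (age −0.45, education 0.3, sex 0.1 on the standardised
  scale) together explain roughly 30% of outcome variance, the order of
  magnitude age and education explain for cognitive test scores in large
  population cohorts; outcome noise 0.84 then keeps total outcome variance
  near 1, so planted screen effects are approximately standardised betas.
* Disease labels, when requested, come from a liability threshold (age +
  confounder + noise) with configurable prevalence, default 10%; no
  published generative disease model exists, so this is package's own
  minimal choice.

Seed discipline: one master seed deterministically spawns per-component
sub-seeds (genotypes, confounder, noises, visits, expression, bootstrap),
so identical configurations are bit-reproducible while components remain
independent.

# Association screen

`fit_association()` regresses the (transformed) cognitive outcome on the
blood measure plus covariates by OLS, or by logistic GLM for the binary
prospective-memory outcome — the link is not dictated by the study design,
and a logistic link is the natural choice for a success/fail measure.
Outcome transforms: natural log for mean reaction time (base is a
convention choice; natural log is used and documented), and
$\log(\mathrm{count}+1)$ for visual-memory mismatch counts because zero
counts occur and a bare log would be undefined. Blood measures can first be
residualised on *technical* covariates (analyser device, acquisition
route) with `residualise_measure()`; when the technical covariates are
orthogonal to the model covariates this two-stage procedure equals the
joint regression, which the tests check to 1e-8.

`run_screen()` applies BH across the full measure-by-outcome grid (one
global family, matching the "all p values were adjusted" reading), not per
outcome. Missing data are handled complete-case per fit with counts
reported; per-fit failures become flagged rows rather than aborting the
grid.

`classify_anaemia()` implements the NICE rule with strict inequalities:
males anaemic below 13 g/100 mL, females below 12 g/100 mL.
`match_case_control()` pairs each case with one unused same-sex control of
nearest age, greedy in seeded random case order, with a ±2-year caliper by
default — the matching procedure itself is under-specified in the source
designs, so the caliper and greedy order are surfaced as arguments.

# Mendelian randomisation

Per SNP, the Wald ratio is $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with
first-order delta-method SE $se(\hat\Gamma_j)/|\hat\gamma_j|$ (second-order
available by flag; the first-order form matches the weights conventionally
used by summary-data MR software).

* **IVW**: $\hat\beta = \sum w_j \hat\beta_j / \sum w_j$, $w_j = 1/se_j^2$,
  fixed-effect $se = (\sum w_j)^{-1/2}$; identical to WLS of $\Gamma$ on
  $\gamma$ through the origin with weights $se(\Gamma)^{-2}$, and the test
  suite checks that identity against an independent QR-based oracle to
  1e-10. A multiplicative random-effects variant ($se$ inflated by
  $\max(1,\hat\sigma)$) is behind a flag. With one instrument the fit
  *is* the Wald ratio, returned identically.
* **Weighted median**: order the ratios, form cumulative normalised weights
  $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum w_k$, interpolate where $s$
  crosses 0.5; SE by parametric bootstrap of $(\hat\gamma_j,
  \hat\Gamma_j)$ from their normal sampling distributions under a required
  seed. Consistent while valid instruments carry more than half the
  weight.
* **MR-Egger**: WLS of $\Gamma$ on $\gamma$ with a free intercept after
  orienting all $\gamma_j > 0$; the intercept estimates directional
  pleiotropy, the slope remains a causal estimate under InSIDE.
  Fixed-effect SEs from the weighted normal equations; p-values from the
  normal approximation by default with a $t_{m-2}$ option.

95% intervals use $z = 1.959964$ throughout. `harmonise()` aligns
two-sample summary tables on the exposure's effect allele, flipping
outcome signs for swapped alleles and dropping strand-ambiguous A/T and
C/G palindromes by default (no frequency-based rescue — at the allele
frequencies of interest frequency inference is unreliable, and dropping is
the conservative default). `filter_instruments()` retains info score
strictly above 0.9, removes listed variants (e.g. a known
outcome-association list such as the APOE/TOMM40 region for dementia
outcomes) and variants inside excluded BED regions (0-based, half-open).
The phrase "median weighted or two-stage least squares" conflates two
estimators; the weighted median is implemented as described and
individual-level two-stage least squares is offered separately as
`mr_tsls()`.

## Estimator calibration

Calibration experiments (Egger intercept type-I error, weighted-median
robustness) use `simulate_summary_instruments()`, which draws
$\hat\gamma_j \sim N(\gamma_j, se_\gamma^2)$ and $\hat\Gamma_j \sim
N(\beta\gamma_j + \alpha_j, se_\Gamma^2)$ directly — the standard
summary-level construction for calibrating these estimators over hundreds
of replicates. Parameter recovery is additionally checked end-to-end at the
individual level: 100–200 replicates of $n = 20{,}000$ cohorts with 30
SNPs and $\beta = 0.05$, where the mean IVW estimate stays within
[0.045, 0.055] and empirical 95% CI coverage within [0.90, 0.98].

# Longitudinal rates of change

`per_subject_slope()` fits `measure = b0 + b1 * age + e` per subject by
OLS. The default minimum is three visits, with two allowed by argument —
the two conventions coexist in practice (two points determine a line but
give no residual), and both are supported with the discrepancy surfaced
rather than hidden. `compare_groups()` uses the Welch (unequal-variance)
t-test — "unpaired t test" does not pin the variance assumption, and Welch
is the safer default — plus the two-sample KS test, with BH applied within
each test family across measures. `mmse_extremes_split()` takes
`floor(n * fraction)` subjects per tail (n = 53 at 20% gives 10 per
extreme) with ties broken by stable subject-id order.

A numerical subtlety: with equal group sizes the two-sample KS statistic
lives on a coarse lattice (multiples of 1/n), so its exact null p-values
are visibly discrete and cannot pass a strict uniformity test. The
calibration experiments therefore use near-equal coprime group sizes
(35 vs 36), which makes the D lattice dense and the null p-distribution
effectively continuous; this is a property of the KS statistic, not of the
implementation.

# Pathway enrichment

`gene_model_stat()` computes per-gene OLS t-statistics of expression on the
trait (all genes through one QR decomposition); moderated/empirical-Bayes
statistics are deliberately not used because the enrichment stage consumes
only the gene-level ranking and significance. `gene_permutation_stat()`
gives permutation p-values for per-gene trait correlations with the
add-one estimator, bounded below by $1/(1+n_{perm})$ and deterministic
under a fixed seed. `ks_enrichment()` compares in-set versus out-of-set
gene statistics with a two-sided two-sample KS test — the background is
all *scored* genes outside the set, not the whole genome — skipping sets
with fewer than 10 scored members and applying BH across tested sets.
Which gene-level quantity feeds the KS comparison (the statistic or its
significance value) is genuinely ambiguous in the source description; both
are supported via the `stat_col` argument, with the model statistic as the
default. The expression generator plants
`effect_size * z(trait) + N(0,1)` in the chosen pathway, so planted genes
have trait correlation $e/\sqrt{1+e^2}$ (0.447 at the default 0.5).

# Pipeline and determinism

`run_pipeline()` drives simulate → associate → mr → rates → enrich from a
single (YAML-able) configuration with one master seed; each stage writes
TSV tables shaped like the study's summary tables (screen grid, per-method
MR estimates, per-measure group tests), a per-SNP diagnostics table for
funnel-style symmetry checks, and a provenance record (stage, inputs,
seed, package version — deliberately no timestamps, so identical configs
give byte-identical output trees, which the tests assert). A failing stage
marks its dependents skipped but leaves independent stages running.

# What the simulations do and do not show

The generator emulates the *statistical* structure the analysis assumes:
additive independent instruments, linear confounding, linear age trends,
pathway-structured expression. Passing tests therefore demonstrate the
estimators are correct and calibrated under that structure at realistic
problem sizes. They do not validate robustness to linkage disequilibrium,
instrument selection on the same data (winner's curse), non-linear
confounding, informative missingness, visit-frequency bias, or microarray
preprocessing artefacts — all of which real cohort data may contain.

## Problem sizes used in validation

Validation uses $n = 20{,}000$ subjects × 30 SNPs (100–200 replicates)
for MR recovery; 300–500 summary-level replicates for estimator
calibration; 10 × 5 screen grids over 100–200 replicates ($n$ = 500 null /
10,000 planted); 71 subjects × 3 visits for rates; and 2,000 genes × 40
samples × 20 gene sets over 50–100 replicates for enrichment. These sizes
were chosen so each Monte-Carlo band in the tests is several times wider
than its standard error.

# Known limitations

* Fixed-effect IVW/Egger SEs assume the per-SNP outcome SEs are known;
  with few, heterogeneous instruments the random-effects flag is the
  safer choice.
* The weighted-median bootstrap treats per-SNP estimates as independent
  normals; in one-sample designs $\hat\gamma_j$ and $\hat\Gamma_j$ share
  sampling noise, which the bootstrap ignores (the effect is second-order
  at the instrument strengths used here).
* Greedy nearest-neighbour matching is order-dependent by construction;
  the seeded shuffle makes it reproducible, not optimal.
* The enrichment KS test treats genes as independent; co-expression within
  pathways inflates its type-I error on real arrays.
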