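---
title: "Methods: two-sample MR, mediation and colocalization in summarymr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation and colocalization in summarymr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summarymr)
```

## The causal model

`summarymr` estimates the causal effect of an exposure X (for example a
microbial abundance or a metabolite concentration) on an outcome Y (a
binary disease state, on the log-odds scale) from two independent GWAS
summary-statistics tables. For each genetic instrument $g_i$ the tables
provide the marginal per-allele effects $\hat\beta_{GX,i}$ and
$\hat\beta_{GY,i}$ with standard errors. Under the instrumental-variable
assumptions (relevance, independence from confounders, and no pathway to
the outcome other than through the exposure), each instrument yields a
consistent ratio estimate

$$\hat\theta_i = \hat\beta_{GY,i} / \hat\beta_{GX,i},
\qquad \mathrm{se}(\hat\theta_i) = \mathrm{se}(\hat\beta_{GY,i}) / |\hat\beta_{GX,i}|,$$

the first-order delta approximation that treats the exposure effect as
known. With one instrument this *is* the estimator (the Wald ratio; the
single-instrument case is what `run_full()` labels cis-MR). With $k \ge 2$
instruments the inverse-variance-weighted (IVW) estimator pools the
ratios with weights $w_i = 1/\mathrm{se}(\hat\theta_i)^2$:

$$\hat\theta = \frac{\sum_i w_i \hat\theta_i}{\sum_i w_i},\qquad
\mathrm{se}_{\mathrm{fixed}}(\hat\theta) = \Big(\sum_i w_i\Big)^{-1/2}.$$

Cochran's $Q = \sum_i w_i (\hat\theta_i - \hat\theta)^2$ on $k-1$ degrees
of freedom measures disagreement among instruments. The default IVW mode
is *multiplicative random effects*: the fixed-effect SE is inflated by
$\max\{1, \sqrt{Q/(k-1)}\}$, so over-dispersed instrument sets yield
wider intervals while the SE never drops below the fixed-effect value.
The fixed mode is retained (`mode = "fixed"`) because its arithmetic is
directly checkable against hand-computed weighted means, and because the
single-exposure multivariable fit reduces to it exactly.

MR-Egger regresses $\hat\beta_{GY,i}$ on $\hat\beta_{GX,i}$ *with an
intercept*, weights $1/\mathrm{se}(\hat\beta_{GY,i})^2$, after flipping
each instrument pair so the exposure effect is non-negative. A non-zero
intercept estimates the average direct (pleiotropic) instrument effect on
the outcome per exposure-increasing allele. The intercept SE uses the
analytic WLS covariance scaled by the square root of the residual
over-dispersion, floored at 1 — the same convention as the IVW SE floor.
All MR p-values are two-sided normal; with the instrument counts this
package targets (up to a few dozen) the normal approximation to the t
reference is a deliberate simplification, slightly anti-conservative
below about ten instruments.

## Decision rules

Instruments are screened at four p-value levels, $p < 10^{-5}$ to
$p < 10^{-8}$ with strict inequality, and reported per level; the levels
are nested, so differences between levels expose sensitivity to
instrument strength. Screened candidates are clumped greedily: the
lowest-p candidate is kept and all others with $r^2 \ge$ `r2_threshold`
(default 0.001) within `window_bp` (default 10 Mb) of it are removed,
repeating until exhaustion. Ties on p are broken by smaller genomic
position, then variant id, making the output deterministic; re-clumping
a clumped set is a no-op. The defaults are the common stringent
convention for polygenic MR; both are exposed because no single choice
suits all LD structures.

An exposure survives to downstream analysis when its MR p-value is below
0.05 *and* there is no evidence of heterogeneity (Q p > 0.05) *and* no
evidence of directional pleiotropy (Egger intercept p > 0.05). A
diagnostic that the instrument count cannot support (Q needs $k \ge 2$,
the intercept $k \ge 3$) counts as a pass — a single-instrument result
is filtered on its p-value alone. Single-instrument (cis) results are
additionally Bonferroni-adjusted, $p_{adj} = \min(1, p \cdot m)$ with
$m$ the number of exposures tested in the same family (configurable;
e.g. 131 for a family of taxa, 452 for metabolites).

## Harmonization policy

Exposure and outcome rows for the same variant are aligned to the
exposure's effect allele. Swapped alleles flip the outcome beta (and
EAF); strand flips (A↔T, C↔G complements) are aligned without sign
change. Palindromic variants (A/T, C/G) are undecidable from alleles
alone: they are dropped when either trait's EAF is missing or within
±0.08 of 0.5 (`palindrome_eaf_window`), and otherwise oriented by
whether the two EAFs fall on the same side of 0.5. These are package
policy, chosen as the common conservative field conventions;
harmonization is involution-safe (re-harmonizing an aligned pair changes
nothing).

## Mediation and multivariable MR

For an exposure E, candidate mediator M and outcome O, the scan runs
univariable MR for E→M, M→E, M→O and E→O and assembles a triangle when
E→M, M→O and E→O are all significant at the (configurable, unadjusted)
0.05 edge gate. The proportion mediated is the product of coefficients
over the total effect,

$$\rho_M = \frac{\beta_{EM}\,\beta_{MO}}{\beta_{EO}},$$

reported as a percentage to one decimal. Values outside [0%, 100%]
(inconsistent mediation — opposite-sign indirect and total effects, or
an indirect effect exceeding the total) are reported with a warning, not
suppressed. When the reverse edge M→E is also significant the triangle
is flagged `ambiguous` rather than filtered out: the package flags
direction rather than silently imposing one. No standard error for
$\rho_M$ is computed (point proportions only); a two-step product-of-
coefficients SE is a possible extension.

Multivariable MR regresses outcome betas on the matrix of $m$ exposures'
betas over the union of their clumped instruments (each exposure's beta
looked up for every union variant), no intercept, weights
$1/\mathrm{se}(\hat\beta_{GY})^2$. The union construction, rather than
each exposure's own list, is a documented choice: it keeps one design
matrix and one weight vector per model. Rank deficiency is reported as a
collinearity error naming the offending exposures. Exposures are marked
retained at p < 0.1, and "adjusted by" effects (the primary exposure's
coefficient conditional on its mediators) reuse the same fit.

## Colocalization

For a ±50 kb region (closed interval; the flank is configurable) the
Wakefield approximate Bayes factor for each variant and trait is

$$\log \mathrm{ABF} = \tfrac12 \log\frac{V}{V+W} + \frac{z^2\,W}{2(V+W)},$$

with $V$ the squared SE, $z$ the Wald statistic, and $W$ the squared
prior effect SD (`prior_sd`, default 0.2 for quantitative traits and
0.15 for binary-trait log-odds). Under the single-causal-variant
assumption the five hypothesis weights are $H_0: 1$;
$H_1: p_1 \sum BF_1$; $H_2: p_2 \sum BF_2$;
$H_3: p_1 p_2 (\sum BF_1 \sum BF_2 - \sum BF_1 BF_2)$;
$H_4: p_{12} \sum BF_1 BF_2$, normalized to posteriors. Priors default
to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the standard field
convention). All accumulation is in log space with log-sum-exp, and the
$H_3$ difference uses a guarded `log1p(-exp(b-a))`, so thousands of
variants with $z$ beyond 30 cannot overflow. No conditioning or masking
for multiple causal variants is attempted.

## What the synthetic data emulate — and what they do not

The generator simulates summary statistics directly rather than
individual-level genotypes: estimated betas are drawn around their true
marginal values with the sampling SE implied by sample size $n$ and
effect-allele frequency $f$,

$$\mathrm{se}_{\mathrm{quant}} = \frac{1}{\sqrt{2f(1-f)\,n}}, \qquad
\mathrm{se}_{\mathrm{binary}} = \frac{1}{\sqrt{2f(1-f)\,n\,\phi(1-\phi)}},$$

with $\phi$ the case fraction — the standard large-sample approximations
for a standardized phenotype and a log-odds coefficient. Within an LD
block, both the true marginal effects and the sampling noise propagate
through an AR(1) correlation ($\beta_j = r_{jc}\,\beta_c$; noise drawn
from the correspondingly correlated multivariate normal), so clumping
and colocalization see realistic local structure.

Default scale mirrors the shape of a microbiome-exposure design at desk
scale: 20 exposures with 2–26 instruments each, exposure GWAS of 18,473
samples, and one binary outcome. The outcome GWAS is set to n = 50,000
with case fraction 0.1 — a stand-in chosen so that per-variant outcome
SEs (~0.02) make single-dataset inference informative at this scale; a
population-scale case-control imbalance would require proportionally
larger simulated cohorts for the same power, without changing any
estimator property being tested. Instrument effects default to
0.08–0.25 SD per allele so that instruments clear the screening levels
at the exposure sample size. Directional pleiotropy is planted relative
to the exposure-increasing allele, matching what the Egger intercept
estimates after orientation; balanced pleiotropy is zero-mean normal.

The mediation generator plants E→M→O paths with a configurable direct
effect; the default path coefficients (0.25, 0.4, 0.2333) imply a true
proportion mediated of exactly 30%. Its default sample sizes
(18,473 / 7,824 / 50,000) keep the exposure's instruments *below* the
screening threshold in the mediator's GWAS — as for the weak
microbe-to-metabolite effects the design mimics — so the mediator's
screened instruments stay distinct from the exposure's. The
larger configuration used in validation (60 exposure instruments,
n = 500,000 / 12,000 / 1,000,000) was sized by a power analysis of the
three edge estimates so that the recovered proportion's sampling SD is
about 2.5 percentage points. The colocalization generator uses the
fixed validation conditions: 200 variants, AR(1) ρ = 0.9, n = 50,000
per trait, causal effect 0.08 SD.

What the generator does **not** emulate: genotype-level sampling (so no
weak-instrument finite-sample artefacts beyond beta measurement error),
sample overlap between the two GWAS, population stratification,
winner's-curse selection of instruments discovered in the same data, and
non-normal phenotypes. Passing tests therefore demonstrate correctness
of the estimators and decision rules under the stated sampling model,
not robustness to those real-data pathologies.

## Numerical and degenerate-input choices

- A zero exposure beta makes the Wald ratio undefined and is an error;
  IVW refuses $k < 2$ (directing to the Wald ratio) and Egger $k < 3$.
- A zero total effect makes $\rho_M$ undefined (error); a zero E→M
  effect yields 0%.
- Screening uses strict `<` at every level; the region window and the
  clumping window are closed intervals.
- Clumping ties on p are broken by position then id; variants missing
  from the LD matrix are an error naming the variant.
- Rows violating the per-variant invariants (SE ≤ 0, p outside (0,1],
  non-ACGT or identical alleles, EAF outside [0,1]) are dropped on
  construction with a counted, messaged reason — not silently repaired.
- Reproducibility: every generator output is a pure function of
  (config, seed); the pipeline itself is deterministic given its inputs.

## Validation problem sizes

The shipped validation uses 1,000 null datasets (k = 10) for IVW type-I
error, 200 datasets (k = 20, θ = 0.5) for recovery, 300/400 datasets
(k = 25) for the Egger power and null-calibration checks, 3 replicate
triangles per mediation setting, 20 regions per colocalization setting,
and one 20-exposure pipeline run — sizes chosen to pin each property
with comfortable Monte-Carlo margins while keeping a full run in the
order of a minute.

## Known limitations

- No weighted-median, mode-based or outlier-robust (MR-PRESSO-style)
  estimators; the heterogeneity/pleiotropy filter is the only defence
  against invalid instruments.
- No F-statistic or conditional-F weak-instrument diagnostics.
- No proxy-variant lookup: exposure and outcome tables must share
  variant ids.
- Colocalization assumes at most one causal variant per trait per
  region.
- The Egger intercept test's normal reference is anti-conservative at
  small instrument counts.
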