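# summarymr

Two-sample Mendelian randomization (MR), mediation and colocalization
from GWAS summary statistics — with a built-in generator of synthetic
summary statistics with known causal architecture, so the whole pipeline
can be exercised and validated without any external data download.

## The problem

Observational associations between molecular exposures (for example gut
microbial abundances or plasma metabolite concentrations) and a disease
outcome are confounded. Two-sample MR uses genetic variants as
instrumental variables: a variant strongly associated with an exposure is
effectively randomized at conception, so the ratio of its outcome effect
to its exposure effect estimates a causal effect, using nothing but
published per-variant association tables from two different cohorts.

`summarymr` implements the full analysis chain:

- **Instrument selection** — screen candidate variants at four
  significance levels (p < 1e-5 … 1e-8, strict inequality) and reduce
  them to LD-independent representatives by greedy clumping (lowest p
  first, removing neighbours with r² ≥ 0.001 within 10 Mb).
- **Harmonization** — align exposure and outcome tables to a shared
  effect allele, recognising allele swaps and strand flips, and dropping
  palindromic variants whose allele frequency cannot resolve the strand
  (EAF within ±0.08 of 0.5, or missing).
- **Univariable MR** — with a single instrument the Wald ratio
  β = β_GY / β_GX with delta-method SE ("cis-MR"); with k ≥ 2 instruments
  the inverse-variance-weighted (IVW) mean of per-instrument ratios with
  weights w_i = 1/se_i² ("polygenic MR"), Cochran's
  Q = Σ w_i (β_i − β̂)² heterogeneity test, and for k ≥ 3 the MR-Egger
  intercept test for directional pleiotropy.
- **Decision rules** — keep exposures with MR p < 0.05 and no evidence of
  heterogeneity or pleiotropy (Q p > 0.05, Egger intercept p > 0.05,
  inapplicable diagnostics pass); Bonferroni-adjust single-instrument
  results over the exposure family.
- **Mediation** — bi-directional MR among surviving traits assembles
  exposure → mediator → outcome triangles and reports the proportion
  mediated ρ_M = (β_EM × β_MO) / β_EO as a percentage.
- **Multivariable MR** — joint weighted least squares of outcome effects
  on several exposures' instrument effects, for direct
  (mediator-adjusted) effects, with a p < 0.1 retention rule.
- **Colocalization** — Wakefield approximate Bayes factors
  log ABF = ½·log(V/(V+W)) + z²·W/(2(V+W)) combined over a ±50 kb region
  into posterior probabilities PP.H0–PP.H4 of no/one-trait/distinct/shared
  causal variants under the single-causal-variant assumption.

## Worked example

```r
library(summarymr)

# 4 synthetic exposures (2 with true effect theta = 0.5 on a binary outcome)
sim <- simulate_exposure_outcome(sim_config(n_exposures = 4, n_causal = 2, seed = 7))
res <- run_univariable_mr(sim$exposures$exposure_01, sim$outcome, sim$ld,
                          levels = c("e5", "e8"))
res[, c("method", "level", "nsnp", "beta", "se", "or_", "p_mr", "Q_pval", "p_pleio")]
#>   method level nsnp  beta     se  or_    p_mr Q_pval p_pleio
#> 1    ivw    e5   11 0.426 0.0448 1.53 1.7e-21  0.813   0.903
#> 2    ivw    e8   11 0.426 0.0448 1.53 1.7e-21  0.813   0.903
```

The planted log-odds effect 0.5 is recovered (0.426 ± 0.045, within 2 SE)
with no heterogeneity (Q p = 0.81) or pleiotropy (intercept p = 0.90);
the odds ratio 1.53 means each SD of the exposure multiplies the odds of
the outcome by about 1.5. Effect-scale conversion matches hand
arithmetic:

```r
effect_to_or_ci(-0.346, 0.135)   # OR 0.708, 95% CI 0.543-0.922
bonferroni_adjust(7.0e-4, 131)   # 0.0917
```

Colocalization of a simulated region whose two traits share one causal
variant (200 variants, AR(1) LD ρ = 0.9, n = 50,000 per trait):

```r
cs <- simulate_coloc_region(shared = TRUE, seed = 1)
coloc_posteriors(cs$region)
#> <coloc_result> 200 variants; priors p1=0.0001 p2=0.0001 p12=1e-05
#> PP.H0 PP.H1 PP.H2 PP.H3 PP.H4
#>     0     0     0     0     1
```

`run_full()` chains every stage (screen → clump → harmonize → MR →
filter → Bonferroni → mediation → MVMR → coloc) and writes
`mr_results.tsv`, `mediation_triangles.tsv`, `mvmr_results.tsv`,
`coloc_results.tsv` and a structured `run.log`. A thin command-line
wrapper lives in `inst/cli/summarymr.R` (subcommands `simulate`, `mr`,
`coloc`, `run-all`).

## Scope

The package operates entirely on summary statistics: no individual-level
genotypes, no VCF parsing, no external LD reference panels, no eQTL
database queries, and no enrichment analysis. LD is supplied as an
r-squared matrix (from the generator or a file).
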