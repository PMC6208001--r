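# brainagesim

Simulation and analysis of age-adjusted BrainAGE associations.

## The problem

Brain-age studies predict chronological age from imaging features and call
the gap between predicted and chronological age **BrainAGE** (Brain Age Gap
Estimate). Because every regression is subject to regression toward the
mean, BrainAGE is *always* negatively correlated with age — young ages are
overestimated, old ages underestimated. Any covariate that merely
correlates with age therefore shows a spurious association with BrainAGE.
`brainagesim` is for methodologists and imaging statisticians who want to
quantify this failure mode under a known ground truth and verify the two
standard repairs: add chronological age to the downstream regression, or
residualize BrainAGE on age first (**BrainAGER**).

## What it does

* **Generative cohort simulation.** Ages ~ U(20, 80); 16 covariates
  `Z_ij = Σ_m α_mj f_m(A_i) + ε_ij` built from three monotone-decreasing
  age basis functions f₁ (linear), f₂ (exponential), f₃ (sigmoid), using
  all 8 ABF subsets twice — 8 covariates feed back into the imaging
  features, 8 matched twins do not; 100 age-related voxel features
  `v_ik = Σ_m (w_mk + D_i) f_m(A_i) + ε_ik` with per-participant departures
  `D_i = γ Σ_{j≤8} Z_ij`, plus 25% pure-noise background features. The
  effect size is a calibrated weight fold change
  `FC = 1 + mean(D)/(σ_w √(2/π))` (1.255 = large, 1.170 = small, 1 = null).
* **Age model.** Radial-kernel support vector regression (e1071 defaults),
  50/50 train/validation split; BrainAGE = predicted − chronological age;
  BrainAGER = OLS residual of BrainAGE on age (exactly zero mean and age
  correlation).
* **Inference.** Joint regressions of BrainAGE on all covariates with and
  without age; per-covariate positive rates and TP/FP aggregates across
  replicates; Benjamini–Hochberg FDR covariate screens for simulated or
  user-supplied tables; closed-form regression-toward-the-mean results
  (`corr(y, residual) = σ_ε/√(σ_X² + σ_ε²)` and friends).

## Worked example

```r
library(brainagesim)

out <- run_replicate(sim_config(), seed = 42)
out$prediction
#> Age prediction on validation set
#>   n = 500, MAE = 5.02 y, R^2 = 0.871 (corr^2 = 0.876)
#>   corr(age, BrainAGE) = -0.517, slope(pred ~ age) = 0.815
```

The validation half of 1,000 simulated participants is predicted to about
5 years mean absolute error. The slope below 1 and the negative
age-BrainAGE correlation are regression toward the mean at work: this
cohort's BrainAGE carries a large age component before any covariate has
had a chance to act. The two repair routes give identical covariate
coefficients, to machine precision:

```r
test <- out$split$test
fwl_equivalence_check(out$prediction$brainage, out$prediction$brainager,
                      out$cohort$Z[test, ], out$cohort$ages[test])$max_deviation
#> [1] 4.718448e-16
```

A replicated two-scenario experiment (the package's main entry point):

```r
res <- run_experiment(sim_config(), output_dir = "run",
                      n_replicates = 50, base_seed = 2018)
res$fc_1.255$rate_summary
#> Positive rates over 50 replicates at alpha = 0.05
#>   tp_rate: with_age = 0.530, without_age = 0.145
#>   fp_rate: with_age = 0.070, without_age = 0.455
```

Read: without age in the model, the age-dependent covariates that have *no*
causal path to the brain reject at 45% — pure confounding. Adding age drops
them to ≈ 7%, near the nominal 5%, while more than tripling power for the
truly contributing covariates. All tables (long-format associations, rates,
−log(p) quartiles, prediction summaries, manifest) are written under
`run/` as commented CSV/YAML.

The same pipeline is scriptable: `Rscript inst/cli/brainagesim.R simulate
--replicates 50 --seed 2018 --out run`, plus `screen` (FDR screen of any
CSV with `age`, `predicted_age` and covariate columns) and `theory-demo`.

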