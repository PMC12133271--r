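# auxmi — multiple imputation with incomplete auxiliary variables

Auxiliary variables (predictors used in an imputation model but not in the
analysis model) are the standard advice for reducing bias and recovering
information in multiple imputation (MI). In practice they are often
incomplete themselves, and their own missing data — its amount *and* its
mechanism — changes what MI delivers. `auxmi` implements a complete
simulation laboratory for this question, aimed at biostatisticians and
epidemiologists designing imputation strategies for cohort data:

* **Synthetic data**: a trivariate normal (outcome `y`, exposure `x`,
  auxiliary `z`) with means (6, −3, 2), unit variances, corr(x, y) = 0.6,
  corr(x, z) = 0, corr(y, z) ∈ {0.1, …, 0.7}, plus a completely observed
  proxy `w = standardize(0.6·z + e)`; deterministic CDF-cutoff missingness
  in `y` (three mechanisms: caused by `x` and `z`, by `y` itself, or by
  `x` only) and in `z` (MCAR, by its own value, or by `w`).
* **Imputation engine**: fully conditional specification (chained
  equations) with proper Bayesian normal-linear draws — residual variance
  from a scaled inverse chi-square, coefficients from their normal
  posterior, fresh noise per cell — and flexible power/product terms
  (`z^3`, `z^3*edu`) rebuilt passively every cycle.
* **Estimation**: complete records analysis (CRA), MI excluding or
  including the auxiliary, Rubin's-rules pooling with both the
  large-sample fraction of missing information λ = (1 + 1/m)B/T and the
  df-adjusted FMI = (r + 2/(ν+3))/(r+1).
* **Orchestration**: the full 360-cell design grid with per-cell derived
  seeds, simsum-style metrics (bias, empirical SE, Monte Carlo SEs, mean
  FMI, bias relative to CRA with a near-zero-denominator flag), YAML
  configs, CSV/JSON outputs and relative-bias panel plots.

The analysis model throughout is the unadjusted regression of `y` on `x`;
with unit variances its true slope is 0.6.

## Worked example

Fifty percent of outcomes missing because of exposure *and* auxiliary
(mechanism 1 — a collider-selected observed sample), auxiliary missing by
its own value (MNAR) for 50% of records, corr(y, z) = 0.7:

```r
library(auxmi)
cfg <- scenario_config(n = 1000, outcome_mech = 1, aux_mech = 2,
                       rho_yz = 0.7, pi_z = 0.5, seed = 2026)
set.seed(derive_seed(cfg$seed, 1))
complete <- generate_complete(cfg)
obs <- observe_dataset(complete,
                       impose_missing_outcome(complete),
                       impose_missing_aux(complete))
cra_fit(obs)
#> <fit_result> slope 0.2721 (SE 0.0298), n = 510, df = 508

stack <- fcs_impute(obs[c("y", "x", "z", "w")], mi_model_specs(aux_mech = 2),
                    fcs_config(m = 20, burnin = 10, seed = 1))
mi_estimate(stack)
#> <pooled_estimate> m = 20
#>   estimate 0.4067, total SE 0.0318 (95% CI 0.3432 to 0.4702)
#>   between 0.00051, within 0.00048, r 1.1193, nu 68.1
#>   lambda 0.5281, FMI 0.5414
```

CRA is badly biased (slope 0.27 against a truth of 0.6) because selection
on a function of `x` and `z` induces a spurious x–z–y path. MI with the
auxiliary recovers part of it (0.41) but not all — half the auxiliary is
missing exactly where it is most needed. The FMI of 0.54 says over half
the information about the slope is still lost. Replicating the scenario
quantifies this:

```r
cfg$n_sim <- 200
res <- run_scenario(cfg, fcs_config(m = 20, burnin = 10))
summarize_scenario(res)[, c("model", "bias", "empse", "mcse_bias",
                            "mean_fmi", "rel_bias_cra")]
#>      model   bias  empse mcse_bias mean_fmi rel_bias_cra
#> 1      cra -0.321 0.0295   0.00208       NA        100.0
#> 2   mi_aux -0.186 0.0278   0.00197    0.405         57.8
#> 3 mi_noaux -0.321 0.0304   0.00215    0.500        100.0
```

MI without the auxiliary tracks CRA exactly; MI with the half-missing MNAR
auxiliary removes only ~42% of the CRA bias (it removes all of it when the
auxiliary is complete).

Whole-grid runs use a YAML config (`read_grid_config()` shows the schema):

```r
cmd_simulate("grid.yaml", "results/")          # metrics.csv, estimates.csv, manifest.json
cmd_plot("results/metrics.csv", "figures/")    # relative-bias panels per mechanism pair
cmd_impute("data.csv", "models.yaml", "mi/")   # generic chained-equations front-end
```

A thin shell wrapper for the same three commands is installed at
`system.file("cli", "auxmi.R", package = "auxmi")`.

## Further reading

The methods vignette (`vignettes/auxiliary-missingness.Rmd`) documents the
data-generating model, the reading of the dual-CDF missingness rule, the
proper-imputation algorithm, both FMI variants, the Monte Carlo error
budget at desk scale, and known limitations.
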