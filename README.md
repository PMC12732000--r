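# adentropy

Entropy-guided machine learning for anaerobic-digestion (AD) operation:
soft-sensor modelling of biogas yield, reactor temperature and volatile
fatty acid (VFA) concentration from routinely measured plant variables,
with information-theoretic uncertainty quantification and a simulated
advisory-operation campaign.

## Who this is for

Process engineers and modellers working on data-driven monitoring of
industrial digesters. Plant SCADA datasets are rarely shareable, so the
package ships a first-class synthetic plant-data generator whose marginal
moments, correlation structure, operating regimes and sensor-fault rate
are configured explicitly — every downstream method is developed and
tested against it.

## What it computes

For a model with held-out residuals `e = y − ŷ`:

- **Error entropy** `H(e) = −∫ p_e(ξ) ln p_e(ξ) dξ` (nats), with `p_e`
  estimated by Gaussian-kernel KDE under Silverman's bandwidth
  `h = 0.9·min(sd, IQR/1.34)·n^{−1/5}`. Lower H(e) = more concentrated
  residuals = higher predictive certainty, beyond what RMSE shows.
- **Permutation entropy increase** `ΔH_j = H(e^{(j)}) − H(e)`, the rise in
  error entropy after permuting feature `j` — an information-theoretic
  feature-contribution measure, cross-checked against random-forest
  importance shares and permutation ΔRMSE.
- **Process entropy** `S_proc = −Σ_k π_k ln π_k` over four discrete
  operating states (normal, VFA accumulation, overload, temperature
  deviation), `0 ≤ S_proc ≤ ln 4`; lower = more ordered operation.
- **Stability** of a campaign as the coefficient of variation
  `CV = sd/mean` of hourly biogas yield, daily CV indices, the relative
  improvement `(CV_baseline − CV_assisted)/CV_baseline`, and a Welch
  t-test on the daily indices.

Around these sit the supporting stages: a Gaussian-copula generator with
truncated-normal marginals and a calibrated nonlinear response kernel;
cleaning/min–max scaling/7:2:1 splitting with Kolmogorov–Smirnov checks
and Pearson feature selection; SVM (RBF), random-forest and neural-network
predictors under one protocol; k-fold and rolling-window evaluation; and
techno-economic scaling (`cost ∝ capacity^0.65`), discounted payback and
grid-emission-factor carbon accounting.

## Worked example

```r
library(adentropy)

cfg <- generator_config()                       # calibrated defaults
rec <- generate_records(cfg, 10000, seed = 1)   # 5-min plant records
nf  <- rec[!rec$fault_flag, ]
cor(nf$feed_solids, nf$biogas_yield)            # 0.900
mean(nf$biogas_yield)                           # 79.53 m3/t
sum(rec$fault_flag)                             # 230 sensor faults

invars <- plant_variables()[1:6]; outs <- plant_variables()[7:9]
cln <- remove_outliers(rec)$table
sp  <- split_records(cln)                       # chronological 7:2:1
np  <- minmax_fit(sp$train, c(invars, outs))
tr  <- minmax_apply(sp$train, np); va <- minmax_apply(sp$validation, np)
te  <- minmax_apply(sp$test, np)

rf <- fit_model(rf_spec(), tr[, invars], tr$biogas_yield, seed = 1)
round(rf_importance(rf), 3)
#>    feed_solids organic_matter      feed_rate             ph
#>          0.562          0.218          0.134          0.011
#>   dissolved_o2   total_solids
#>          0.009          0.067

ann <- fit_model(ann_spec(max_epochs = 150), tr[, invars], tr[, outs],
                 X_val = va[, invars], y_val = va[, outs],
                 norm_params = np, seed = 1)
# test RMSE (biogas): 1.14 m3/t; H(e): ANN -2.086 < RF -2.015 nats

base <- simulate_operation(cfg, NULL, weeks = 12, seed = 11)
asst <- simulate_operation(cfg, advisory_policy(ann), weeks = 12, seed = 11)
base
#> <scenario_result> baseline, 12 weeks (seed 11)
#>   hourly-yield CV: 18.1%   S_proc: 1.294 nats
asst
#> <scenario_result> assisted (gain 1.00, lead 1 h), 12 weeks (seed 11)
#>   hourly-yield CV: 4.8%   S_proc: 0.075 nats
stability_improvement(base$cv, asst$cv)         # 0.73
```

The feed variables (feed solids, organic matter, feed rate) carry ~91 % of
the forest's importance; the network is both the most accurate and the
most certain predictor (lowest error entropy); and the one-hour-ahead
advisory policy cuts hourly-yield variability from ~18 % to under 5 %,
collapsing process entropy because operation stays in the normal state.

An end-to-end runner is also provided:

```r
run_pipeline(default_run_config(), outdir = "ad_run", seed = 1)
```

(or `Rscript inst/scripts/ad-pipeline.R --config inst/extdata/default_config.yaml`),
writing per-stage CSV artifacts and JSON manifests.

## Package layout

- `R/synth_plant.R` — generator: copula, truncated marginals, calibrated
  response kernel, regimes, faults, CSV I/O
- `R/preprocess.R` — cleaning limits, min–max scaling, splits, K–S,
  Pearson matrix, feature selection
- `R/models.R` — SVM / random forest / neural-network specs and fits,
  grid search
- `R/evaluate.R` — classification & regression metrics, AUROC, CV,
  rolling windows, importances, permutation ΔRMSE
- `R/entropy.R` — error entropy, entropy increase, operating states,
  process entropy
- `R/operation.R` — disturbance model, advisory policy, campaign
  simulator, stability statistics
- `R/tea_lca.R` — capacity scaling, discounted payback, carbon accounting
- `R/pipeline.R` — staged runner with manifests

The methods vignette (`vignettes/entropy-guided-ad.Rmd`) documents the
model assumptions, calibration choices, parameter defaults and
limitations.
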