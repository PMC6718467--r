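# restreward

Predicting ventral-striatal reward activation from resting-state
functional connectivity.

## The problem

Ventral-striatum (VS) activation during reward anticipation, measured
with the monetary incentive delay (MID) task, is a standard readout of
neural gain processing — but the task is hard to administer in many
populations and differs between sites. A task-free alternative is to
predict the VS response from resting-state functional connectivity (FC).
`restreward` implements that full analysis as a tested R package for
methodologists who want to study when and how well such prediction works:
a seeded synthetic multi-site cohort generator with recorded ground
truth, the MID first-level GLM, the reward-sensitivity slope model,
nuisance-cleaned Pearson connectivity with permutation group inference,
relevance vector regression (RVR) with cross-validation and permutation
significance, and network-level decomposition of the model weights.

## The core model

Three per-subject targets are derived from the gain-anticipation
contrasts (amount vs. 0 yen): reward **sensitivity** — the slope `b1` of
`value = b0 + b1·rank` over ranks 1 (¥20), 2 (¥100), 3 (¥500) — plus the
**maximal** (¥500 vs ¥0) and **average** (mean gain vs ¥0) contrasts.
Each target is predicted from the vectorised FC edge features through
RVR, a sparse Bayesian linear model over `Phi = [1 | K]` (linear kernel
`K`, per-basis precisions `alpha`):

    Sigma   = (sigma^-2 Phi'Phi + diag(alpha))^-1      posterior covariance
    mu      = sigma^-2 Sigma Phi' y                    posterior mean
    gamma_i = 1 - alpha_i Sigma_ii
    alpha_i <- gamma_i / mu_i^2                        evidence update
    sigma^2 <- ||y - Phi mu||^2 / (n - sum gamma)

Basis functions with `alpha > 1e12` are pruned; the survivors are the
relevance vectors. Generalisation is assessed with an estimation
(n = 30) / held-out (n = 15) split stratified over the three sites and
10-fold cross-validation (27/3) inside the estimation set; raw scores get
an affine scaling correction fitted on the estimation set only, and
significance comes from permuting the estimation targets and rerunning
the whole CV. Edge-space weights (averaged over the 10 fold models and
the full-set model) are refolded to an ROI × ROI matrix and aggregated
over the seven functional networks plus basal ganglia and cerebellum.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic conditions. The prediction step:

```sh
Rscript analysis/04_predict_rvr.R
```

prints (default seed, 999 permutations):

```
Estimation n = 30 | holdout n = 15
sensitivity  estimation r = 0.36 (p = 0.179), MSE = 0.14 | holdout r = 0.43, MSE = 0.15
maximal      estimation r = 0.40 (p = 0.129), MSE = 1.48 | holdout r = 0.48, MSE = 1.09
average      estimation r = 0.66 (p = 0.004), MSE = 0.78 | holdout r = 0.27, MSE = 1.25
```

Under the default conditions the targets carry noise equal to the signal
(oracle ceiling r ≈ 0.7), so correlations around 0.3–0.5 with MSEs on VS
contrast-unit scales are the expected regime; setting
`noise_sd_target = 0` in the generator makes the mapping exactly
recoverable and the same pipeline reaches holdout r > 0.9 for all three
measures. The weight decomposition step reports, for the sensitivity
model,

```
sensitivity  top nodes in: DM DM DM DM DM | largest network cell: DM-DM
```

i.e. the learned contributions concentrate in the default-mode network,
where the generator planted them. Equivalent calls in R:

```r
library(restreward)
cohort <- simulate_cohort(seed = 1)                  # 45 subjects, 3 sites
res <- run_full_analysis(cohort, list(n_perm = 999, seed = 1))
res$measures$sensitivity$r_holdout
W <- refold_weights(res$measures$sensitivity$averaged_weight_vector, 40)
network_aggregate(W, cohort$roi_set$network_label)
```

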