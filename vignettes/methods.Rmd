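---
title: "Predicting ventral-striatal reward activation from resting connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ventral-striatal reward activation from resting connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Ventral-striatum (VS) activation during reward anticipation — classically
measured with the monetary incentive delay (MID) task — is a widely used
readout of neural gain circuits, but the task is demanding for many
populations and varies across sites. `restreward` implements and tests a
task-free alternative: predicting three per-subject summaries of VS
reward anticipation (reward *sensitivity*, *maximal*-reward response,
*average*-reward response) from resting-state functional connectivity
(FC) with relevance vector regression (RVR). Because no public cohort
exists for the original multi-site design, the package is built around a
seeded synthetic-cohort generator with recorded ground truth, so every
stage of the pipeline can be validated against known answers.

## Task model and VS measures

Each MID trial is cue → jittered anticipation interval → speeded target
→ feedback. Two first-level schemes are supported:

* `two_run_gain_loss`: two concatenated runs of 90 trials (40 gain, 40
  loss, 10 neutral; amounts ±0/20/100/500 yen), modelled with 24
  condition regressors — 8 anticipation conditions, 2 control events
  (neutral cue/feedback), 12 amount × hit/miss feedback regressors and a
  common feedback regressor per ±0 yen condition.
* `one_run_gain`: one run of 62 win + 18 neutral trials, modelled with 14
  regressors — 4 gain anticipation conditions, 8 amount × hit/miss
  feedback regressors and the 2 control events. (The single-run protocol
  is described as 90 trials although its condition counts sum to 80; the
  generator follows the explicit 62 + 18 counts.)

Condition regressors are boxcars convolved with the canonical
double-gamma HRF (peak delay 6 s, undershoot delay 16 s, dispersions 1,
peak:undershoot 6, unit peak), built at 1/16-TR microtime resolution
separately within each run; six motion parameters and one intercept per
run complete the design. Estimation is ordinary least squares;
rank-deficient designs fall back to the minimum-norm solution with a
warning.

Four contrasts are formed against the 0-yen anticipation condition
(small = 20, medium = 100, maximal = 500, average = equal thirds of the
three amounts), and three measures are derived per subject:

* `sensitivity`: slope `b1` of the OLS line `value = b0 + b1 * rank` over
  ranks 1 (=20), 2 (=100), 3 (=500). Rank rather than yen amount is the
  regressor because the VS response is closer to linear in rank; for
  equally spaced ranks the slope equals `(maximal − small) / 2` exactly.
* `maximal`: the 500-vs-0 contrast value.
* `average`: the mean-gain contrast value (identically the mean of the
  three pairwise contrasts).

At the voxel level, `sphere_roi_values()` averages a value grid over
merged spheres (boundary-inclusive Euclidean membership, union before
averaging, optional grey-matter mask), matching the bilateral 6-mm VS
sphere construction at MNI (12, 10, −4) / (−10, 10, −6).

## Resting-state processing

Cleaning is a single combined regression per subject: intercept, six
motion parameters, the first three principal components of the WM and of
the CSF signal matrices, and sine/cosine regressors at every discrete
frequency `m/(T·tr)` strictly below 0.01 Hz or strictly above 0.1 Hz
(stop-band modelled as nuisance; the all-zero Nyquist sine is dropped).
Because it is one projection, the operation is idempotent and removes any
signal lying in the nuisance span exactly. FC is the Pearson correlation
matrix of the residual series; negative correlations are kept as they
are, and no Fisher transformation is applied to the features (a `fisher_z`
option exists for the group-inference stage only).

Group inference on the mean FC matrix uses independent random sign flips
of each subject's matrix as the null (exact under elementwise sign
symmetry — the natural resampling scheme for a "zero connectivity" null),
with family-wise error controlled by the permutation distribution of the
maximum absolute mean, `p = (1 + #{max-stat ≥ |observed|}) / (1 + n_perm)`.

## Relevance vector regression

Edge features are the strict upper triangle of the FC matrix in row-major
order (`n(n−1)/2` values). A linear kernel is built with centering
statistics from the training subjects only. The RVR model places one
precision hyperparameter `alpha_i` on each column of `Phi = [1 | K]`
(bias plus one basis function per training subject) and iterates the
evidence-maximisation updates

    Sigma  = (sigma^-2 Phi' Phi + diag(alpha))^-1
    mu     = sigma^-2 Sigma Phi' y
    gamma_i = 1 − alpha_i Sigma_ii
    alpha_i <- gamma_i / mu_i^2
    sigma^2 <- ||y − Phi mu||^2 / (n − sum gamma)

pruning basis functions whose precision exceeds 1e12 and stopping when
the largest change in `log(alpha)` drops below 1e-6 (default cap 1000
sweeps). Initialisation is `alpha = 1/n^2`, `sigma^2 = 0.1·var(y)` —
common stable defaults, both configurable. The noise variance is floored
at `1e-12` of the target scale (variance, with the mean square as
fallback for degenerate constant targets) so that interpolating fits stay
finite. The bias carries its own precision, so it is unpenalised in
effect. The marginal likelihood is tracked per sweep; the sweep itself is
implemented in compiled code (RcppArmadillo) with the identical update
order as the documented equations, and the test suite checks it against
an independent explicit-inversion R implementation, against the ridge
closed form under clamped hyperparameters, and for evidence monotonicity
and scale equivariance.

For linear kernels the dual solution folds back to feature space,
`w = sum_i mu_i (x_i − x̄)`, with the bias adjusted for centering so that
`predict ≡ X w + bias` holds to machine precision — this is what lets
edge-space weights be refolded into ROI × ROI matrices.

## Cross-validation, scaling and significance

Subjects are split into an estimation sample (n = 30) and a held-out
sample (n = 15), allocated over the three sites proportionally with
largest-remainder rounding (14/15/16 → 5/5/5 held out), then the
estimation sample is divided into 10 folds of 3 for cross-validation
(27 train / 3 test per fold). Per measure:

* *Estimation ("training-runs") performance* is computed on the
  concatenated out-of-fold predictions. The aggregate is not uniquely
  pinned down by the original description, which plots per-fold points;
  concatenation is the documented choice here and is configurable in the
  sense that all per-fold raw scores are returned.
* *Weight averaging*: the primal weight vectors of the 10 fold models and
  of the complete-estimation-set model are averaged with equal weight
  (11 terms).
* *Scaling correction* regresses actual on raw scores over the
  estimation set only and applies the affine map everywhere; Pearson r is
  unchanged by construction (affine invariance), only MSE is affected.
  The held-out raw scores come from the averaged weight vector, and their
  scaling regression is fitted on the averaged-weight raw scores of the
  estimation subjects — held-out subjects never influence kernel
  centering, fold models or scaling.
* *Permutation significance* permutes targets across estimation subjects
  only, reruns the complete CV + scaling + evaluation with the same fold
  structure, and applies the add-one counting rule (right tail for r,
  left tail for MSE). Held-out p-values, when requested, rerun the full
  averaged-weight pipeline per permutation against the untouched held-out
  targets and are labelled as such — whether the original held-out
  p-values used the same scheme is not documented, so this artifact
  defines its own.

Default `n_perm` is study-scale 10,000 for the FC inference and a
desk-scale 999 in the analysis drivers; the acceptance checks use reduced
counts (199–499) with wide calibration bands.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` mirrors the three-site structure: 14/15/16 subjects,
resting TR 2.5/2.0/2.7 s with 120/143/107 retained volumes, task TR 2 s,
schemes two-run gain/loss at sites 1 and 3 and one-run gain at site 2.

* **Resting signal.** Per site, a block correlation matrix (within-network
  0.5, between 0.1) over 40 ROIs labelled with the seven functional
  networks plus basal ganglia and cerebellum (DM largest, 8 ROIs). Each
  subject perturbs every network's within-block coupling (sd 0.2) and
  every network-pair coupling (sd 0.1) — subject-level coupling variation
  is what makes individual differences in FC more than sampling noise,
  and is the signal the prediction feeds on. Non-positive-definite block
  matrices are repaired by eigenvalue clipping and rescaling (recorded).
  Innovations are Gaussian with AR(1) temporal filtering (lag-1 0.3),
  scaled to keep the stationary covariance equal to the block matrix —
  the minimal temporally correlated noise model.
* **Confounds.** Six random-walk motion parameters and exactly-rank-3 WM
  and CSF signal matrices are mixed linearly into the ROI series with
  recorded coefficients, so the combined nuisance regression is testable
  for exact removal.
* **Targets.** Sparse ground-truth edge weights concentrate on the
  within-DM block (shared, strongly overlapping patterns for sensitivity
  and maximal — which makes those two targets empirically correlated —
  and a DM-plus-DM–VA mixture for average). Weight columns are rescaled
  so the noiseless predictors sit on realistic VS contrast-unit scales
  (sd 0.3/0.8/1.0). Targets are the inner product of each subject's
  *cleaned* FC features with the weights plus Gaussian noise whose sd is
  `noise_sd_target` times the predictor sd (default 1, giving an oracle
  ceiling near r ≈ 0.7, of the order of the originally reported 0.38–0.54;
  0 gives an exactly recoverable mapping). Anticipation amplitudes are
  then constructed per subject so that the noiseless first-level GLM
  reproduces exactly these targets, closing the loop from task series to
  measures.
* **Not emulated:** voxel-level images, scanner drift/spike artifacts
  beyond AR(1), behavioural reaction times, and any nonlinearity between
  FC and activation. Passing tests therefore demonstrate correctness of
  the estimation machinery and calibration of the inference under the
  stated generative model — not that real resting data carry this much
  predictive signal.

Block-coherent support was a deliberate design choice: contributions
coherent over network blocks are both how the weight-matrix decomposition
reads the model out and what keeps the mapping identifiable from 30
training subjects; with isolated random edges the target would load on
edgewise sampling noise that no learner could recover at this sample
size.

## Numerical and design notes

* Edge ordering (row-major strict upper triangle) is asserted by an exact
  vectorise/refold round trip; ranking ties break by index.
* Node sums and network aggregation use absolute weights by default
  (signed variants behind a flag): the weight matrix does not by itself
  say whether connectivity increases or decreases the predicted measure.
* The resting ROI radius is stored as configuration (default 6 mm); the
  source description is ambiguous between 6- and 10-mm spheres for
  signal extraction, and nothing in the ROI-level pipeline depends on it.
* WM/CSF components default to 3 per tissue (6 total); the alternative
  3-total reading is reachable via `n_pcs`.
* Kernel centering defaults to on; the uncentred variant is exposed since
  toolbox preprocessing conventions differ.
* Anticipation epochs span cue onset to target onset; per-event second
  timings are configurable stand-ins (cue 0.5 s, anticipation 2–2.5 s
  jittered, target 0.5 s, feedback 1.65 s).
* Problem sizes in the test suite and acceptance checks: 40 ROIs / 780
  edges, 45 subjects, 199–999 permutations, 10,000-volume simulations
  for Monte-Carlo consistency checks — chosen to make the full validation
  cycle run on a single CPU in minutes while keeping every statistical
  property testable.

## Known limitations

* The generator's linear FC→activation mapping is an assumption, not a
  finding; real cohorts may violate it in ways the tests cannot detect.
* Performance metrics on 15 held-out subjects have wide sampling
  variability; the package reports them as the study design dictates but
  calibration statements rest on the repeated-replicate tests.
* No site-harmonisation (e.g. ComBat), nested hyperparameter tuning or
  alternative learners: the pipeline deliberately matches the original
  analysis rather than optimising it.
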