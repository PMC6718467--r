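#!/usr/bin/env Rscript
# Step 4 — predict the VS measures from resting connectivity.
#
# Splits the cohort into estimation (n = 30) and held-out (n = 15) samples
# stratified by site, runs 10-fold cross-validated relevance vector
# regression per measure, corrects prediction scaling with the
# estimation-set regression, evaluates Pearson r and MSE on the
# out-of-fold and held-out predictions, and attaches permutation
# p-values (999 permutations of the estimation targets).
# Writes per-subject prediction tables, averaged weight vectors and
# metrics JSON under results/prediction/.

suppressMessages(library(restreward))
seed <- 1L

cohort <- simulate_cohort(seed = seed)
res <- run_full_analysis(cohort, list(n_perm = 999, seed = seed))
write_prediction_results(res, "results/prediction")

cat("Estimation n =", length(res$plan$estimation_ids),
    "| holdout n =", length(res$plan$holdout_ids), "\n")
for (meas in names(res$measures)) {
  m <- res$measures[[meas]]
  cat(sprintf(
    "%-12s estimation r = %.2f (p = %.3f), MSE = %.2f | holdout r = %.2f, MSE = %.2f\n",
    meas, m$r_train, m$p_r, m$mse_train, m$r_holdout, m$mse_holdout))
}
cat("Wrote results/prediction/ (predictions, weights, metrics.json)\n")
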