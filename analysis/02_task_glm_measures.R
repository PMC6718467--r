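#!/usr/bin/env Rscript
# Step 2 — first-level MID GLM and the three VS measures.
#
# Fits the per-subject task GLM (24 or 14 condition regressors plus motion
# and run intercepts), forms the four gain-anticipation contrasts and
# derives sensitivity (rank slope), maximal and average reward measures.
# Writes results/vs_measures.tsv and reports the empirical correlation
# between sensitivity and the maximal-reward response.

suppressMessages(library(restreward))
seed <- 1L

cohort <- simulate_cohort(seed = seed)
tg <- cohort_targets(cohort, source = "glm")

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(data.frame(subject_id = rownames(tg), tg),
                 "results/vs_measures.tsv")

cat("Fitted the first-level GLM for", nrow(tg), "subjects\n")
cat(sprintf("Measure SDs: sensitivity %.3f, maximal %.3f, average %.3f\n",
            sd(tg[, 1]), sd(tg[, 2]), sd(tg[, 3])))
cat(sprintf("cor(sensitivity, maximal) = %.3f\n",
            cor(tg[, "sensitivity"], tg[, "maximal"])))
cat("Wrote results/vs_measures.tsv\n")
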