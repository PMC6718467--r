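test_that("ROI sets are labelled, bounded and deterministic", {
  rs <- make_roi_set(9, networks = setNames(rep(1L, 9),
                                            restreward:::network_levels()),
                     seed = 1)
  expect_equal(sort(unique(rs$network_label)),
               sort(restreward:::network_levels()))
  expect_length(rs$network_label, 9)

  r1 <- make_roi_set(40, seed = 7)
  r2 <- make_roi_set(40, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$n_roi * (r1$n_roi - 1) / 2, 780)
  expect_true(all(is.finite(r1$coordinates)))
  expect_true(all(r1$coordinates[, "x"] >= -70 &
                    r1$coordinates[, "x"] <= 70))
  expect_error(make_roi_set(1), "at least 2")
})

test_that("block covariance has the stated pattern and stays PD", {
  rs <- make_roi_set(4, networks = c(DM = 2, VI = 2), seed = 2)
  C <- make_rest_cov(rs, within_net_r = 0.5, between_net_r = 0)
  blocks <- outer(rs$network_label, rs$network_label, "==")
  expect_true(all(C[blocks & row(C) != col(C)] == 0.5))
  expect_true(all(C[!blocks] == 0))
  expect_equal(diag(C), rep(1, 4))

  expect_equal(unclass(make_rest_cov(rs, 0, 0))[1:4, 1:4], diag(4),
               ignore_attr = TRUE)

  rs40 <- make_roi_set(40, seed = 3)
  C40 <- make_rest_cov(rs40, 0.5, 0.1)
  expect_gt(min(eigen(C40, symmetric = TRUE, only.values = TRUE)$values), 0)

  expect_error(make_rest_cov(rs, 0.5, 0.9), "must not exceed")
  expect_error(make_rest_cov(rs, 1.2, 0), "inside")
})

test_that("simulated rest series reproduce their covariance", {
  rs <- make_roi_set(10, networks = c(DM = 5, VI = 5), seed = 4)
  cov <- make_rest_cov(rs, 0.5, 0)
  sim <- simulate_rest_ts(cov, 10000, 2.5, ar_coef = 0, seed = 5,
                          confound_strength = 0)
  C <- fc_matrix(sim$latent)
  blocks <- outer(rs$network_label, rs$network_label, "==") & upper.tri(C)
  expect_lt(abs(mean(C[blocks]) - 0.5), 0.02)

  # identity covariance: off-diagonal correlations near zero
  sim0 <- simulate_rest_ts(diag(10), 5000, 2.5, ar_coef = 0, seed = 6,
                           confound_strength = 0)
  C0 <- fc_matrix(sim0$latent)
  expect_lt(mean(abs(C0[upper.tri(C0)])), 0.05)

  s1 <- simulate_rest_ts(cov, 100, 2.5, seed = 8)
  s2 <- simulate_rest_ts(cov, 100, 2.5, seed = 8)
  expect_identical(s1, s2)
  expect_error(simulate_rest_ts(cov, 10, 2.5), "at least 20")
  expect_error(simulate_rest_ts(cov, 100, 2.5, ar_coef = 1), "ar_coef")
})

test_that("AR(1) filtering leaves cross-correlations intact", {
  rs <- make_roi_set(6, networks = c(DM = 3, VI = 3), seed = 9)
  cov <- make_rest_cov(rs, 0.6, 0.1)
  sim <- simulate_rest_ts(cov, 8000, 2, ar_coef = 0.4, seed = 10,
                          confound_strength = 0)
  C <- fc_matrix(sim$latent)
  expect_lt(max(abs(C - cov)), 0.06)
  # and the series really is autocorrelated
  ac <- mean(apply(sim$latent, 2, function(x) cor(x[-1], x[-8000])))
  expect_gt(ac, 0.3)
})

test_that("MID designs carry the documented trial counts", {
  d <- make_mid_design("two_run_gain_loss", seed = 11)
  tab <- table(d$trials$type, d$trials$run)
  expect_equal(as.vector(tab[, 1]), c(40, 40, 10))
  expect_equal(as.vector(tab[, 2]), c(40, 40, 10))
  amounts <- table(d$trials$amount[d$trials$type == "gain"])
  expect_equal(as.vector(amounts), rep(20, 4))

  d2 <- make_mid_design("one_run_gain", seed = 12)
  expect_equal(sum(d2$trials$type == "gain"), 62)
  expect_equal(sum(d2$trials$type == "neutral"), 18)

  # onsets strictly increasing and inside the stated duration
  expect_true(all(diff(d$events$onset_s) >= 0 |
                    diff(sort(d$events$onset_s)) >= 0))
  expect_true(max(d$events$onset_s + d$events$duration_s) <= d$duration_s)

  # hit indicator matches the calibrated rate
  set.seed(13)
  hits <- unlist(lapply(1:80, function(i) {
    make_mid_design("two_run_gain_loss")$trials$hit
  }))
  expect_lt(abs(mean(hits) - 0.66), 0.015) # ~4 sd at 14,400 trials
})

test_that("target linking is exact at zero noise and noisy otherwise", {
  set.seed(14)
  rs <- make_roi_set(8, networks = c(DM = 4, VA = 2, VI = 2), seed = 15)
  gt <- make_ground_truth(rs, noise_sd_target = 0, seed = 16)
  d <- 28
  F <- matrix(rnorm(3 * d), 3, d)
  tg <- link_targets(F, gt)
  expect_equal(tg, F %*% gt$true_edge_weights, ignore_attr = TRUE)

  # one-hot weights pick out a single edge value
  gt1 <- gt
  gt1$true_edge_weights <- matrix(0, d, 3,
    dimnames = list(NULL, c("sensitivity", "maximal", "average")))
  gt1$true_edge_weights[11, ] <- 1
  expect_equal(unname(link_targets(F, gt1)[, "maximal"]), F[, 11])

  expect_error(link_targets(F[, 1:5], gt), "does not match")

  # shared support induces correlated sensitivity and maximal targets
  coh <- simulate_cohort(small_cohort_config(n_per_cohort = c(10, 10, 10)),
                         seed = 17)
  tg2 <- coh$ground_truth$targets
  expect_gt(cor(tg2[, "sensitivity"], tg2[, "maximal"]), 0.5)
})

test_that("prediction ceiling decreases monotonically with target noise", {
  oracle_r <- sapply(c(0, 0.5, 1, 2), function(ns) {
    coh <- simulate_cohort(small_cohort_config(
      n_per_cohort = c(8, 8, 8), noise_sd_target = ns), seed = 18)
    F <- coh$ground_truth$linking_features
    W <- coh$ground_truth$true_edge_weights
    cor(drop(F %*% W[, "sensitivity"]),
        coh$ground_truth$targets[, "sensitivity"])
  })
  expect_true(all(diff(oracle_r) < 0))
  expect_equal(oracle_r[1], 1)
})

test_that("whole cohorts are reproducible and well-formed", {
  c1 <- simulate_cohort(small_cohort_config(), seed = 19)
  c2 <- simulate_cohort(small_cohort_config(), seed = 19)
  expect_identical(c1$ground_truth$targets, c2$ground_truth$targets)
  expect_identical(c1$subjects[[5]]$rest_ts, c2$subjects[[5]]$rest_ts)

  expect_length(c1$subjects, 9)
  s <- c1$subjects[[1]]
  expect_false(anyNA(s$rest_ts))
  expect_equal(ncol(s$motion), 6)
  expect_gt(nrow(s$rest_ts), ncol(s$motion) + 10)

  # cohort with task: GLM-derived measures equal linked targets at 0 noise
  c3 <- simulate_cohort(list(
    n_per_cohort = c(2, 2, 2), n_roi = 10,
    networks = c(VI = 2, VA = 2, DM = 4, BG = 1, CB = 1),
    rest_vols = c(80, 80, 80), rest_tr = c(2.5, 2, 2.7),
    noise_sd_target = 0, noise_sd_task = 0
  ), seed = 20)
  tg_glm <- cohort_targets(c3, source = "glm")
  expect_equal(tg_glm, c3$ground_truth$targets, tolerance = 1e-8)
})

test_that("cohort writer round-trips series and events as text", {
  coh <- simulate_cohort(list(
    n_per_cohort = c(1, 1, 1), n_roi = 6,
    networks = c(VI = 1, VA = 1, DM = 3, BG = 1),
    rest_vols = c(60, 60, 60), rest_tr = c(2.5, 2, 2.7),
    noise_sd_task = 0
  ), seed = 21)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(man), 3)
  ts <- read_timeseries(file.path(dir, "sub01_rest.tsv"))
  expect_equal(unname(ts), unname(coh$subjects[[1]]$rest_ts),
               tolerance = 1e-12)
  ev <- read_events(file.path(dir, "sub01_events.tsv"))
  expect_equal(ev$onset_s, coh$subjects[[1]]$design$events$onset_s,
               tolerance = 1e-12)
  rs <- read_roi_table(file.path(dir, "roi_table.tsv"))
  expect_equal(rs$network_label, coh$roi_set$network_label)
  unlink(dir, recursive = TRUE)
})
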