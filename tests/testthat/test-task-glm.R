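test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.01)
  t <- seq(0, 32, by = 0.01)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # peak near 5 s, single positive lobe followed by one undershoot
  expect_lt(abs(t[which.max(h)] - 5), 0.05)
  signs <- sign(h[abs(h) > 1e-12])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_error(canonical_hrf(0), "positive")
  expect_error(canonical_hrf(-2), "positive")
})

test_that("design matrix carries the scheme's condition regressors", {
  set.seed(4)
  d <- make_mid_design("two_run_gain_loss")
  n_vol <- ceiling((d$duration_s + 20) / 2)
  dm <- build_design_matrix(d, 2, n_vol, motion = matrix(rnorm(n_vol * 6),
                                                         n_vol))
  expect_length(dm$condition_cols, 24)
  expect_equal(ncol(dm$X), 24 + 6 + 2) # conditions + motion + run intercepts

  d2 <- make_mid_design("one_run_gain")
  n_vol2 <- ceiling((d2$duration_s + 20) / 2)
  dm2 <- build_design_matrix(d2, 2, n_vol2)
  expect_length(dm2$condition_cols, 14)

  # condition columns do not depend on motion scaling
  dm_scaled <- build_design_matrix(d, 2, n_vol,
                                   motion = 100 * matrix(1, n_vol, 6))
  expect_equal(dm$X[, dm$condition_cols], dm_scaled$X[, dm$condition_cols])

  # empty event list leaves only motion and intercept columns
  empty <- list(events = d$events[0, ], scheme = "two_run_gain_loss",
                run_start_s = 0)
  dm0 <- build_design_matrix(empty, 2, 50, motion = matrix(0, 50, 6))
  expect_length(dm0$condition_cols, 0)
  expect_equal(ncol(dm0$X), 7)

  bad <- list(events = data.frame(onset_s = 1, duration_s = 1,
                                  condition = "nonsense"),
              scheme = "one_run_gain", run_start_s = 0)
  expect_error(build_design_matrix(bad, 2, 50), "unknown condition")
  late <- list(events = data.frame(onset_s = 200, duration_s = 1,
                                   condition = "neutral_cue"),
               scheme = "one_run_gain", run_start_s = 0)
  expect_error(build_design_matrix(late, 2, 50), "beyond scan end")
})

test_that("GLM recovers noiseless data and flags degeneracy", {
  set.seed(5)
  X <- cbind(1, matrix(rnorm(60 * 4), 60))
  colnames(X) <- c("int", paste0("c", 1:4))
  beta <- c(0.5, -1, 2, 0, 1.5)
  Y <- X %*% beta
  g <- fit_glm(Y, X)
  expect_lt(max(abs(g$betas - beta)), 1e-8)
  expect_equal(g$design_rank, 5)

  g0 <- fit_glm(matrix(0, 60, 2), X)
  expect_true(all(g0$betas == 0))

  Xdup <- cbind(X, dup = X[, 2])
  expect_warning(gd <- fit_glm(Y, Xdup), "rank deficient")
  expect_lt(max(abs(Xdup %*% gd$betas - Y)), 1e-6) # minimum-norm still fits
  expect_error(fit_glm(Y[1:4, , drop = FALSE], X[1:4, ]), "rank")
})

test_that("contrasts are amount-vs-zero differences with exact average", {
  B <- matrix(c(0, 1, 2, 3), 4, 1,
              dimnames = list(paste0("ant_gain_", c(0, 20, 100, 500)), NULL))
  g <- structure(list(betas = B, residual_variance = 0, design_rank = 4),
                 class = "mid_glm")
  cs <- anticipation_contrasts(g)
  expect_equal(cs$small, 1)
  expect_equal(cs$medium, 2)
  expect_equal(cs$maximal, 3)
  expect_equal(cs$average, 2)
  expect_equal(cs$average, mean(c(cs$small, cs$medium, cs$maximal)))

  rownames(B)[1] <- "something_else"
  g2 <- structure(list(betas = B, residual_variance = 0, design_rank = 4),
                  class = "mid_glm")
  expect_error(anticipation_contrasts(g2), "ant_gain_0")
})

test_that("noiseless simulate-fit round trip is exact end to end", {
  set.seed(6)
  for (scheme in c("two_run_gain_loss", "one_run_gain")) {
    d <- make_mid_design(scheme)
    conds <- restreward:::scheme_conditions(scheme)
    betas <- setNames(rnorm(length(conds), 0.4, 0.3), conds)
    betas[paste0("ant_gain_", c(0, 20, 100, 500))] <- c(0.2, 0.45, 0.8, 1.3)
    y <- simulate_task_ts(d, betas, tr = 2)
    g <- fit_glm(y, build_design_matrix(d, 2, nrow(y)))
    cs <- anticipation_contrasts(g)
    expect_lt(abs(cs$small - 0.25), 1e-6)
    expect_lt(abs(cs$medium - 0.6), 1e-6)
    expect_lt(abs(cs$maximal - 1.1), 1e-6)
  }
  # zero amplitudes give a flat series
  d <- make_mid_design("one_run_gain")
  flat <- simulate_task_ts(d, setNames(numeric(14),
                                       restreward:::scheme_conditions("one_run_gain")),
                           tr = 2)
  expect_true(all(flat == 0))
})

test_that("beta recovery degrades with task noise", {
  set.seed(7)
  d <- make_mid_design("one_run_gain")
  conds <- restreward:::scheme_conditions("one_run_gain")
  betas <- setNames(rnorm(length(conds), 0.5, 0.2), conds)
  rmse_at <- function(noise_sd) {
    errs <- replicate(4, {
      y <- simulate_task_ts(d, betas, tr = 2, noise_sd = noise_sd)
      g <- fit_glm(y, build_design_matrix(d, 2, nrow(y)))
      sqrt(mean((g$betas[conds, 1] - betas)^2))
    })
    mean(errs)
  }
  expect_gt(rmse_at(1), rmse_at(0.1))
})

test_that("sphere ROI averaging merges overlapping spheres once", {
  dims <- c(9, 9, 9)
  affine <- rbind(c(2, 0, 0, -8), c(0, 2, 0, -8), c(0, 0, 2, -8),
                  c(0, 0, 0, 1))
  vals <- array(7, dims)
  expect_equal(sphere_roi_values(vals, affine, c(0, 0, 0), 4), 7)

  # brute-force union oracle for two overlapping spheres
  set.seed(8)
  vals <- array(rnorm(prod(dims)), dims)
  centers <- rbind(c(0, 0, 0), c(3, 0, 0))
  idx <- as.matrix(expand.grid(0:8, 0:8, 0:8))
  mm <- idx * 2 - 8
  inside <- rep(FALSE, nrow(mm))
  for (k in 1:2) {
    inside <- inside | sqrt(rowSums(sweep(mm, 2, centers[k, ])^2)) <= 4
  }
  expect_equal(sphere_roi_values(vals, affine, centers, 4),
               mean(as.vector(vals)[inside]))

  # mask intersects before averaging
  mask <- array(FALSE, dims)
  mask[5, 5, 5] <- TRUE
  expect_equal(sphere_roi_values(vals, affine, centers, 4, mask = mask),
               vals[5, 5, 5])
  # off-grid centre with a tiny radius has no member voxels
  expect_error(sphere_roi_values(vals, affine, c(1, 1, 1), 0.5), "empty")
})
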