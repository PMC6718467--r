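test_that("PCA scores recover low-rank structure in variance order", {
  set.seed(20)
  f <- rnorm(50)
  load <- rnorm(6)
  X <- outer(f, load)
  s1 <- pca_components(X, 1)
  expect_gt(abs(cor(s1[, 1], f)), 1 - 1e-10)

  X <- matrix(rnorm(100 * 10), 100, 10)
  sc <- pca_components(X, 10)
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-10))
  # full-rank scores reconstruct the centred matrix exactly
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc)
  expect_lt(max(abs(sc %*% t(sv$v) - Xc)), 1e-8)
  expect_error(pca_components(X, 11), "between 1 and")
})

test_that("spectral regressors cover exactly the stop-band grid", {
  sr <- spectral_regressors(100, 2.5)
  f <- attr(sr, "freq_hz")
  low <- sort(unique(f[f < 0.01]))
  expect_equal(low, c(1, 2) / 250) # 0.004, 0.008 Hz
  expect_true(all(f < 0.01 | f > 0.1))

  # no low-frequency columns when f_lo = 0
  sr0 <- spectral_regressors(100, 2.5, f_lo = 1e-9)
  expect_true(all(attr(sr0, "freq_hz") > 0.1))

  expect_error(spectral_regressors(100, 2.5, f_hi = 0.2), "Nyquist")

  # passband signal is orthogonal to the regressors
  t <- (0:99) * 2.5
  s <- sin(2 * pi * 0.05 * t)
  res <- clean_timeseries(cbind(s), cbind(1, sr))
  expect_gt(var(res[, 1]) / var(s), 0.99)
})

test_that("combined nuisance regression removes injected confounds exactly", {
  set.seed(21)
  rs <- make_roi_set(10, seed = 1)
  cov <- make_rest_cov(rs, 0.5, 0.1)
  sim <- simulate_rest_ts(cov, 90, 2.5, seed = 2)
  N <- nuisance_model(90, 2.5, motion = sim$motion, wm = sim$wm_signals,
                      csf = sim$csf_signals)
  res_obs <- clean_timeseries(sim$ts, N)
  res_latent <- clean_timeseries(sim$latent, N)
  # the injected contamination lies in the nuisance span
  expect_lt(max(abs(res_obs - res_latent)), 1e-8)
  # projection: idempotent
  expect_lt(max(abs(clean_timeseries(res_obs, N) - res_obs)), 1e-10)

  # a pure linear mix of nuisance columns is annihilated
  mix <- N %*% matrix(rnorm(ncol(N) * 3), ncol(N), 3)
  expect_lt(max(abs(clean_timeseries(mix, N))) / max(abs(mix)), 1e-8)
})

test_that("fc_matrix is a guarded Pearson correlation", {
  set.seed(22)
  Y <- matrix(rnorm(200 * 4), 200, 4)
  Y <- cbind(Y, Y[, 1], -Y[, 2])
  C <- fc_matrix(Y)
  expect_equal(C[1, 5], 1)
  expect_equal(C[2, 6], -1)
  expect_equal(diag(C), rep(1, 6))
  expect_equal(C, t(C))
  expect_true(all(C >= -1 & C <= 1))

  Ybad <- cbind(Y, zero_roi = 0)
  expect_error(fc_matrix(Ybad), "zero_roi")
})

test_that("sign-flip maxT inference finds block structure, not null noise", {
  set.seed(23)
  n_roi <- 8
  # null: symmetric zero-mean edge values
  null_mats <- replicate(12, {
    v <- rnorm(n_roi * (n_roi - 1) / 2, 0, 0.2)
    refold_weights(v, n_roi)
  }, simplify = FALSE)
  g0 <- group_fc_inference(null_mats, n_perm = 199, seed = 1)
  expect_true(all(g0$p_fwe >= 0 & g0$p_fwe <= 1))

  zero_mats <- replicate(5, matrix(0, n_roi, n_roi), simplify = FALSE)
  gz <- group_fc_inference(zero_mats, n_perm = 99, seed = 1)
  expect_false(any(gz$sig_mask))

  # powered case: strong within-block connectivity across 20 subjects
  rs <- make_roi_set(10, networks = c(DM = 5, VI = 5), seed = 3)
  cov <- make_rest_cov(rs, 0.5, 0)
  mats <- lapply(1:20, function(i) {
    sim <- simulate_rest_ts(cov, 150, 2.5, confound_strength = 0)
    fc_matrix(sim$latent)
  })
  g1 <- group_fc_inference(mats, n_perm = 499, seed = 2)
  within <- outer(rs$network_label, rs$network_label, "==") &
    upper.tri(g1$p_fwe)
  expect_true(all(g1$sig_mask[within]))
  expect_error(group_fc_inference(mats, n_perm = 0), "n_perm")
})
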