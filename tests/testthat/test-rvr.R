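test_that("linear kernel matches brute-force dot products and centering", {
  set.seed(30)
  X <- matrix(rnorm(12), 4, 3)
  K <- build_kernel(X, center = FALSE)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) ref[i, j] <- sum(X[i, ] * X[j, ])
  expect_equal(unclass(K)[1:4, 1:4], ref)

  # orthonormal rows give the identity
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(unclass(build_kernel(Q, center = FALSE))[1:5, 1:5],
               diag(5), tolerance = 1e-12)

  # centering zeroes row/column sums of the training Gram
  Kc <- build_kernel(X)
  expect_lt(max(abs(rowSums(Kc))), 1e-10)
  expect_lt(max(abs(colSums(Kc))), 1e-10)

  expect_error(build_kernel(X, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("RVR recovers a noiseless sparse dual solution", {
  set.seed(31)
  X <- matrix(rnorm(20 * 8), 20, 8)
  K <- build_kernel(X)
  y <- 1.5 * K[, 7] + 2
  m <- rvr_fit(K, y)
  expect_lt(max(abs(rvr_predict(m, K) - y)), 1e-6)
  expect_lt(length(m$retained), 6) # sparse basis
  expect_true(all(m$alpha > 0))
  expect_gt(m$sigma2, 0)

  # constant targets collapse to a bias-dominated model
  mc <- rvr_fit(K, rep(3.7, 20))
  expect_lt(max(abs(rvr_predict(mc, K) - 3.7)), 1e-6)
})

test_that("clamped RVR equals the ridge closed form", {
  set.seed(32)
  K <- build_kernel(matrix(rnorm(10 * 10), 10, 10), center = FALSE)
  y <- rnorm(10)
  a <- 3
  s2 <- 0.7
  m <- rvr_fit(K, y, alpha_init = a, sigma2_init = s2,
               fixed_alpha = TRUE, fixed_sigma2 = TRUE)
  Phi <- cbind(1, K)
  ridge <- solve(crossprod(Phi) + s2 * a * diag(11), crossprod(Phi, y))
  expect_lt(max(abs(m$mu - ridge)), 1e-8)
})

test_that("RVR matches the explicit-inversion reference on small problems", {
  set.seed(33)
  for (i in 1:4) {
    n <- sample(6:12, 1)
    d <- sample(2:6, 1)
    X <- matrix(rnorm(n * d), n, d)
    K <- build_kernel(X)
    y <- X[, 1] * 2 + rnorm(n, sd = 0.2)
    m <- rvr_fit(K, y)
    o <- rvr_oracle(K, y)
    expect_lt(max(abs(rvr_predict(m, K) - o$predict(K))), 1e-6)
  }
})

test_that("evidence is monotone and the fit is scale-equivariant", {
  set.seed(34)
  X <- matrix(rnorm(18 * 6), 18, 6)
  K <- build_kernel(X)
  y <- X[, 2] - 0.5 * X[, 4] + rnorm(18, sd = 0.3)
  m <- rvr_fit(K, y)
  expect_gt(min(diff(m$evidence)), -1e-8)

  m10 <- rvr_fit(K, 10 * y)
  expect_lt(max(abs(rvr_predict(m10, K) - 10 * rvr_predict(m, K))), 1e-4)

  # pure-noise targets keep fewer relevance vectors than structured ones
  set.seed(35)
  n_rv <- sapply(1:6, function(i) {
    Xi <- matrix(rnorm(30 * 10), 30, 10)
    Ki <- build_kernel(Xi)
    struct <- rvr_fit(Ki, Xi[, 1] * 2)
    noise <- rvr_fit(Ki, rnorm(30))
    c(structured = length(struct$retained), noise = length(noise$retained))
  })
  expect_lt(mean(n_rv["noise", ]), mean(n_rv["structured", ]))
})

test_that("predictions, primal weights and serialisation are consistent", {
  set.seed(36)
  X <- matrix(rnorm(15 * 5), 15, 5)
  K <- build_kernel(X)
  y <- drop(X %*% c(1, 0, -2, 0, 0.5)) + rnorm(15, sd = 0.1)
  m <- rvr_fit(K, y)
  Xnew <- matrix(rnorm(7 * 5), 7, 5)
  Knew <- build_kernel(X, Xnew, xbar = attr(K, "xbar"))
  pw <- rvr_primal_weights(m, X, xbar = attr(K, "xbar"))
  expect_lt(max(abs(rvr_predict(m, Knew) -
                      (drop(Xnew %*% pw$w) + pw$bias))), 1e-8)
  # training rows reproduce fitted values
  expect_equal(rvr_predict(m, K), rvr_predict(m, K[, , drop = FALSE]))
  expect_error(rvr_predict(m, Knew[, 1:2, drop = FALSE]), "expected")

  # bias-only model predicts its bias and has zero primal weights
  mb <- structure(list(mu = 4.2, retained = 0L, n_train = 15),
                  class = "rvr_model")
  expect_equal(rvr_predict(mb, K), rep(4.2, 15))
  pwb <- rvr_primal_weights(mb, X)
  expect_equal(pwb$w, numeric(5))
  expect_equal(pwb$bias, 4.2)

  # single retained sample, no centering: weights are that sample's features
  m1 <- structure(list(mu = c(1), retained = 3L, n_train = 15),
                  class = "rvr_model")
  expect_equal(rvr_primal_weights(m1, X)$w, X[3, ])

  tf <- tempfile(fileext = ".json")
  write_rvr_model(m, tf, xbar = attr(K, "xbar"))
  m2 <- read_rvr_model(tf)
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$retained, m$retained)
  expect_equal(rvr_predict(m2, Knew), rvr_predict(m, Knew))
  unlink(tf)
})
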