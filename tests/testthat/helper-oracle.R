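# Independent slow reference implementation of the sparse-Bayesian
# evidence-maximisation updates: recomputes the posterior by explicit
# matrix inversion (solve) at every sweep, no factorisation reuse.
rvr_oracle <- function(K, y, max_iter = 1000, tol = 1e-6, prune_at = 1e12) {
  Phi <- cbind(1, K)
  n <- length(y)
  M <- ncol(Phi)
  alpha <- rep(1 / n^2, M)
  sigma2 <- max(0.1 * stats::var(y), 1e-8)
  s_floor <- max(1e-12 * stats::var(y), 1e-12 * mean(y^2),
                 .Machine$double.eps^2)
  act <- seq_len(M)
  for (it in seq_len(max_iter)) {
    P <- Phi[, act, drop = FALSE]
    Sig <- solve(t(P) %*% P / sigma2 + diag(alpha[act], length(act)))
    mu <- as.numeric(Sig %*% (t(P) %*% y)) / sigma2
    g <- 1 - alpha[act] * diag(Sig)
    new_alpha <- alpha
    new_alpha[act] <- ifelse(mu^2 > 0, pmax(g, 0) / mu^2, Inf)
    new_s <- max(sum((y - P %*% mu)^2) / max(n - sum(g), 1e-6), s_floor)
    ok <- is.finite(new_alpha[act]) & is.finite(alpha[act]) &
      new_alpha[act] < prune_at
    d <- if (any(ok)) {
      max(abs(log(new_alpha[act][ok]) - log(alpha[act][ok])))
    } else 0
    alpha <- new_alpha
    sigma2 <- new_s
    keep <- is.finite(alpha[act]) & alpha[act] < prune_at
    changed <- !all(keep)
    if (!any(keep)) {
      act <- 1L
      alpha[1L] <- prune_at / 2
      changed <- TRUE
    } else {
      act <- act[keep]
    }
    if (d < tol && !changed) break
  }
  P <- Phi[, act, drop = FALSE]
  Sig <- solve(t(P) %*% P / sigma2 + diag(alpha[act], length(act)))
  mu <- as.numeric(Sig %*% (t(P) %*% y)) / sigma2
  list(
    mu = mu, retained = act - 1L, sigma2 = sigma2,
    predict = function(K_new) {
      as.numeric(cbind(1, K_new)[, act, drop = FALSE] %*% mu)
    }
  )
}

# small fast cohort used by several pipeline tests: 9 subjects over three
# sites, 12 ROIs, short rest scans, no task series
small_cohort_config <- function(...) {
  utils::modifyList(list(
    n_per_cohort = c(3, 3, 3), n_roi = 12,
    networks = c(VI = 1, SM = 1, DA = 1, VA = 2, FT = 1, FP = 1,
                 DM = 3, BG = 1, CB = 1),
    rest_vols = c(80, 80, 80), rest_tr = c(2.5, 2, 2.7),
    simulate_task = FALSE
  ), list(...))
}
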