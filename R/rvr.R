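#' Linear kernel between feature matrices
#'
#' `K = (X_other - xbar)(X_train - xbar)^T`, with the centering statistics
#' taken from the training features only (or supplied via `xbar`, e.g. when
#' forming a test kernel against a previously fitted model).
#'
#' @param X_train `n x d` training features.
#' @param X_other `m x d` features to form kernel rows for (default the
#'   training features themselves).
#' @param center Centre features with training column means (default TRUE).
#' @param xbar Optional pre-computed centering vector (length d).
#' @return `m x n` kernel matrix with attribute `xbar` (the centering
#'   vector used, or NULL).
#' @export
build_kernel <- function(X_train, X_other = X_train, center = TRUE,
                         xbar = NULL) {
  X_train <- as.matrix(X_train)
  X_other <- as.matrix(X_other)
  if (ncol(X_train) != ncol(X_other)) {
    stop("feature dimension mismatch: ", ncol(X_train), " vs ",
         ncol(X_other), call. = FALSE)
  }
  if (center) {
    if (is.null(xbar)) xbar <- colMeans(X_train)
    X_train <- sweep(X_train, 2, xbar)
    X_other <- sweep(X_other, 2, xbar)
  } else {
    xbar <- NULL
  }
  K <- X_other %*% t(X_train)
  attr(K, "xbar") <- xbar
  K
}

#' Relevance vector regression by evidence maximisation
#'
#' Sparse Bayesian linear regression over the basis `Phi = [1 | K]` (an
#' unpenalised-in-effect bias plus one basis function per training sample).
#' Each basis function carries its own precision hyperparameter `alpha_i`;
#' the iterative re-estimation
#' \deqn{\Sigma = (\sigma^{-2}\Phi^T\Phi + diag(\alpha))^{-1},\quad
#'       \mu = \sigma^{-2}\Sigma\Phi^T y,\quad
#'       \gamma_i = 1 - \alpha_i\Sigma_{ii},\quad
#'       \alpha_i \leftarrow \gamma_i/\mu_i^2,\quad
#'       \sigma^2 \leftarrow \|y - \Phi\mu\|^2/(n - \sum_i\gamma_i)}
#' drives most `alpha_i` to infinity; basis functions with
#' `alpha_i > prune_at` are pruned, and the surviving samples are the
#' relevance vectors. Iteration stops when the largest change in
#' `log(alpha)` falls below `tol`.
#'
#' @param K `n x n` kernel matrix (see [build_kernel()]).
#' @param y Length-`n` target vector.
#' @param max_iter Maximum number of update sweeps (default 1000).
#' @param tol Convergence threshold on `max |delta log alpha|` (default 1e-6).
#' @param prune_at Precision above which a basis function is removed
#'   (default 1e12).
#' @param alpha_init Initial precision (default `1/n^2` for every basis).
#' @param sigma2_init Initial noise variance (default `0.1 * var(y)`).
#' @param fixed_alpha,fixed_sigma2 Hold `alpha` / `sigma2` at their initial
#'   values (diagnostic use; with both fixed the posterior mean is the
#'   ridge-regression solution).
#' @return An `rvr_model`: `mu` (posterior mean over retained basis),
#'   `alpha`, `sigma2`, `retained` (0 = bias, otherwise training-sample
#'   index), `gamma`, `n_train`, `iterations`, `converged`,
#'   `max_dlogalpha`, `evidence` (marginal log-likelihood trace).
#' @export
rvr_fit <- function(K, y, max_iter = 1000, tol = 1e-6, prune_at = 1e12,
                    alpha_init = NULL, sigma2_init = NULL,
                    fixed_alpha = FALSE, fixed_sigma2 = FALSE) {
  K <- as.matrix(K)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(K) != n) stop("K rows must match length(y)", call. = FALSE)
  if (n < 3) stop("need at least 3 training samples", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite", call. = FALSE)

  Phi_full <- cbind(bias = 1, K)
  M <- ncol(Phi_full)
  vy <- stats::var(y)
  if (is.null(alpha_init)) alpha_init <- 1 / n^2
  if (is.null(sigma2_init)) sigma2_init <- max(0.1 * vy, 1e-8)
  # floor relative to the target scale (mean square guards constant y)
  sigma2_floor <- max(1e-12 * vy, 1e-12 * mean(y^2), .Machine$double.eps^2)

  PtP <- crossprod(Phi_full)
  Pty <- drop(crossprod(Phi_full, y))
  st <- .rvr_em_core(PtP, Pty, sum(y^2), n, alpha_init, sigma2_init,
                     sigma2_floor, as.integer(max_iter), tol, prune_at,
                     fixed_alpha, fixed_sigma2)
  if (!st$finite_ok) {
    stop("RVR update produced non-finite posterior mean at iteration ",
         st$iterations, call. = FALSE)
  }
  active <- as.integer(st$active)
  alpha <- drop(st$alpha)
  sigma2 <- st$sigma2
  it <- st$iterations
  converged <- st$converged
  max_dla <- st$max_dlogalpha
  evidence <- drop(st$evidence)

  # final posterior for the surviving basis
  Phi <- Phi_full[, active, drop = FALSE]
  a <- alpha[active]
  H <- crossprod(Phi) / sigma2
  diag(H) <- diag(H) + a
  Sigma <- chol2inv(chol(H))
  mu <- drop(Sigma %*% crossprod(Phi, y)) / sigma2
  gamma <- 1 - a * diag(Sigma)

  structure(list(
    mu = mu,
    alpha = a,
    sigma2 = sigma2,
    retained = active - 1L,       # 0 = bias, k >= 1 = training sample k
    gamma = gamma,
    n_train = n,
    iterations = it,
    converged = converged,
    max_dlogalpha = max_dla,
    evidence = evidence
  ), class = "rvr_model")
}

#' Predictions from a fitted RVR model
#'
#' `yhat = Phi_test mu`, where `Phi_test` holds a bias column (if the bias
#' was retained) and the kernel columns of the retained relevance vectors.
#'
#' @param model An `rvr_model`.
#' @param K_test `m x n_train` kernel between test and training features
#'   (columns are subset to the retained samples internally), or an
#'   `m x n_retained` kernel already restricted to the relevance vectors.
#' @return Numeric vector of m predictions.
#' @export
rvr_predict <- function(model, K_test) {
  stopifnot(inherits(model, "rvr_model"))
  K_test <- as.matrix(K_test)
  rv <- model$retained[model$retained > 0]
  if (ncol(K_test) == model$n_train) {
    Kr <- K_test[, rv, drop = FALSE]
  } else if (ncol(K_test) == length(rv)) {
    Kr <- K_test
  } else {
    stop("K_test has ", ncol(K_test), " columns; expected ", model$n_train,
         " (full) or ", length(rv), " (retained)", call. = FALSE)
  }
  Phi <- if (0L %in% model$retained) cbind(1, Kr) else Kr
  drop(Phi %*% model$mu)
}

#' Primal (feature-space) weights of a linear-kernel RVR model
#'
#' Folds the dual solution back into feature space:
#' `w = sum_i mu_i (x_i - xbar)` over the retained training samples, with
#' the bias adjusted for centering so that `predict == X w + bias` exactly.
#'
#' @param model An `rvr_model` fitted on a linear kernel of `X_train`.
#' @param X_train The training feature matrix the kernel was built from.
#' @param xbar Centering vector used for the kernel (the `xbar` attribute
#'   of [build_kernel()] output), or NULL if the kernel was uncentred.
#' @return List with `w` (length-d vector) and `bias`.
#' @export
rvr_primal_weights <- function(model, X_train, xbar = NULL) {
  stopifnot(inherits(model, "rvr_model"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) != model$n_train) {
    stop("X_train rows must match the model's training size", call. = FALSE)
  }
  rv <- model$retained[model$retained > 0]
  mu_s <- model$mu[model$retained > 0]
  mu_b <- if (0L %in% model$retained) model$mu[model$retained == 0] else 0
  if (!is.null(xbar)) X_train <- sweep(X_train, 2, xbar)
  w <- if (length(rv)) {
    drop(crossprod(X_train[rv, , drop = FALSE], mu_s))
  } else {
    numeric(ncol(X_train))
  }
  bias <- mu_b - if (!is.null(xbar)) sum(w * xbar) else 0
  list(w = w, bias = unname(bias))
}

#' Serialise / restore an RVR model as JSON
#'
#' @param model An `rvr_model`.
#' @param path File path; the JSON records `mu`, `alpha`, `sigma2`,
#'   `retained`, `n_train` and optional centering statistics.
#' @param xbar Optional centering vector to store alongside the model.
#' @export
write_rvr_model <- function(model, path, xbar = NULL) {
  stopifnot(inherits(model, "rvr_model"))
  obj <- list(mu = model$mu, alpha = model$alpha, sigma2 = model$sigma2,
              retained = model$retained, n_train = model$n_train,
              xbar = xbar)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rvr_model
#' @return `read_rvr_model` returns the restored `rvr_model` (with the
#'   stored centering vector as attribute `xbar`).
#' @export
read_rvr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- structure(list(
    mu = as.numeric(obj$mu), alpha = as.numeric(obj$alpha),
    sigma2 = obj$sigma2, retained = as.integer(obj$retained),
    n_train = as.integer(obj$n_train)
  ), class = "rvr_model")
  attr(m, "xbar") <- if (!is.null(obj$xbar)) as.numeric(obj$xbar) else NULL
  m
}
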