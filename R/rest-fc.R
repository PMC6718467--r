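#' Principal-component scores of a nuisance signal matrix
#'
#' Columns are centred internally; scores of the top `k` components,
#' ordered by explained variance, are returned (used for the first three
#' WM and CSF components of the tissue-regression model).
#'
#' @param signal_matrix `T x q` matrix.
#' @param k Number of components (`k <= min(T, q)`).
#' @return `T x k` matrix of component scores.
#' @export
pca_components <- function(signal_matrix, k) {
  X <- as.matrix(signal_matrix)
  if (k < 1 || k > min(dim(X))) {
    stop("'k' must be between 1 and min(T, q) = ", min(dim(X)), call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = 0)
  sv$u %*% diag(sv$d[seq_len(k)], k)
}

#' Sine/cosine stop-band regressors for bandpass filtering by regression
#'
#' Bandpass filtering from `f_lo` to `f_hi` Hz is implemented by including
#' one sine and one cosine regressor for every frequency on the discrete
#' grid `m / (T * tr)`, `m = 1..floor(T/2)`, strictly below `f_lo` or
#' strictly above `f_hi`; regressing them out (together with the other
#' nuisance terms, in a single model) removes the stop-band. The all-zero
#' sine at the Nyquist frequency (even `T`) is dropped.
#'
#' @param n_vol Number of volumes `T`.
#' @param tr Repetition time (s).
#' @param f_lo,f_hi Passband edges in Hz (defaults 0.01 and 0.1).
#' @return Matrix of stop-band columns (possibly 0 columns), with a
#'   `freq_hz` attribute giving each column's frequency.
#' @export
spectral_regressors <- function(n_vol, tr, f_lo = 0.01, f_hi = 0.1) {
  if (f_lo < 0 || f_lo >= f_hi) stop("need 0 <= f_lo < f_hi", call. = FALSE)
  if (f_hi >= 1 / (2 * tr)) {
    stop("'f_hi' must be below the Nyquist frequency ", 1 / (2 * tr), " Hz",
         call. = FALSE)
  }
  m <- seq_len(floor(n_vol / 2))
  f <- m / (n_vol * tr)
  keep <- f < f_lo | f > f_hi
  m <- m[keep]
  f <- f[keep]
  t <- (seq_len(n_vol) - 1) * tr
  cols <- list()
  freq <- numeric(0)
  for (i in seq_along(m)) {
    co <- cos(2 * pi * f[i] * t)
    cols[[length(cols) + 1L]] <- co
    freq <- c(freq, f[i])
    si <- sin(2 * pi * f[i] * t)
    if (2L * m[i] != n_vol) { # sine vanishes exactly at Nyquist
      cols[[length(cols) + 1L]] <- si
      freq <- c(freq, f[i])
    }
  }
  out <- if (length(cols)) do.call(cbind, cols) else matrix(0, n_vol, 0)
  if (ncol(out)) {
    colnames(out) <- make.unique(sprintf("f%.4g", freq))
  }
  attr(out, "freq_hz") <- freq
  out
}

#' Assemble the combined nuisance model for resting data
#'
#' One regression model holding the intercept, six motion parameters, the
#' first `n_pcs` principal components of the WM and of the CSF signal
#' matrices, and the spectral stop-band columns. Column count must stay
#' below `T`.
#'
#' @param n_vol,tr Series length (volumes) and repetition time (s).
#' @param motion `T x 6` motion parameters (optional).
#' @param wm,csf Tissue signal matrices (`T x q`, optional).
#' @param n_pcs Components per tissue (default 3).
#' @param f_lo,f_hi Passband edges (Hz); set `bandpass = FALSE` to skip.
#' @param bandpass Include spectral columns (default TRUE).
#' @return Nuisance matrix with an intercept as first column.
#' @export
nuisance_model <- function(n_vol, tr, motion = NULL, wm = NULL, csf = NULL,
                           n_pcs = 3, f_lo = 0.01, f_hi = 0.1,
                           bandpass = TRUE) {
  parts <- list(intercept = matrix(1, n_vol, 1))
  if (!is.null(motion)) parts$motion <- as.matrix(motion)
  if (!is.null(wm)) parts$wm <- pca_components(wm, n_pcs)
  if (!is.null(csf)) parts$csf <- pca_components(csf, n_pcs)
  if (bandpass) parts$spec <- spectral_regressors(n_vol, tr, f_lo, f_hi)
  N <- do.call(cbind, parts)
  if (ncol(N) >= n_vol) {
    stop("nuisance model has ", ncol(N), " columns for only ", n_vol,
         " volumes", call. = FALSE)
  }
  N
}

#' Regress the nuisance model out of ROI time series
#'
#' Residuals of an OLS regression of every ROI column on the full nuisance
#' matrix (single combined model: intercept + motion + tissue PCs +
#' stop-band sines/cosines). The operation is a projection, hence
#' idempotent.
#'
#' @param Y `T x n_roi` series.
#' @param nuisance Nuisance matrix from [nuisance_model()].
#' @return Residual series, same dimension as `Y`.
#' @export
clean_timeseries <- function(Y, nuisance) {
  Y <- as.matrix(Y)
  N <- as.matrix(nuisance)
  if (nrow(Y) != nrow(N)) stop("Y and nuisance rows differ", call. = FALSE)
  qn <- qr(N)
  if (qn$rank >= nrow(N)) {
    stop("nuisance model rank (", qn$rank, ") leaves no residual degrees ",
         "of freedom", call. = FALSE)
  }
  res <- qr.resid(qn, Y)
  dimnames(res) <- dimnames(Y)
  res
}

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time series. Negative
#' correlations are kept as they are; no thresholding or sign removal is
#' applied.
#'
#' @param clean_ts `T x n_roi` (cleaned) series.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(clean_ts) {
  Y <- as.matrix(clean_ts)
  v <- apply(Y, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- colnames(Y)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance ROI column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  C <- stats::cor(Y)
  (C + t(C)) / 2
}

#' Group-level elementwise inference on mean connectivity
#'
#' The statistic is the elementwise mean correlation across subjects
#' (optionally after Fisher z-transformation). The null of zero
#' connectivity is simulated by independent random sign flips of each
#' subject's matrix (exact under elementwise sign symmetry); family-wise
#' error across edges is controlled through the permutation distribution of
#' the maximum absolute statistic, two-sided:
#' `p = (1 + #\{max-stat >= |observed|\}) / (1 + n_perm)`.
#'
#' @param matrices List of symmetric FC matrices (equal dimension), or a
#'   3-D array `n_roi x n_roi x n_subj`.
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param alpha Significance level for the mask (default 0.05).
#' @param seed Optional RNG seed.
#' @param fisher_z Average Fisher z-transformed values (default FALSE).
#' @return List: `mean_r` (matrix), `p_fwe` (matrix, 1 on the diagonal),
#'   `sig_mask` (`p_fwe <= alpha`, FALSE on the diagonal), `alpha`,
#'   `n_perm`.
#' @export
group_fc_inference <- function(matrices, n_perm = 10000, alpha = 0.05,
                               seed = NULL, fisher_z = FALSE) {
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  if (is.array(matrices) && length(dim(matrices)) == 3) {
    matrices <- lapply(seq_len(dim(matrices)[3]), function(i) matrices[, , i])
  }
  n_sub <- length(matrices)
  if (n_sub < 2) stop("need at least 2 subjects", call. = FALSE)
  n_roi <- nrow(matrices[[1]])
  S_r <- t(vapply(matrices, vectorize_fc, numeric(n_roi * (n_roi - 1) / 2)))
  S <- if (fisher_z) atanh(pmin(pmax(S_r, -1 + 1e-12), 1 - 1e-12)) else S_r
  obs <- colMeans(S)
  if (!is.null(seed)) set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                  n_perm, n_sub)
  perm_stats <- (signs %*% S) / n_sub
  max_t <- apply(abs(perm_stats), 1, max)
  p <- vapply(abs(obs), function(o) (1 + sum(max_t >= o)) / (1 + n_perm),
              numeric(1))
  mean_mat <- refold_weights(colMeans(S_r), n_roi) # reported on the r scale
  diag(mean_mat) <- 1
  p_mat <- refold_weights(p, n_roi)
  diag(p_mat) <- 1
  mask <- p_mat <= alpha
  diag(mask) <- FALSE
  list(mean_r = mean_mat, p_fwe = p_mat, sig_mask = mask,
       alpha = alpha, n_perm = n_perm)
}
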