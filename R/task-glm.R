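#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with the standard parameterisation
#' (response peak delay 6 s, undershoot delay 16 s, dispersions 1,
#' peak-to-undershoot ratio 6), sampled every `tr` seconds over
#' `duration_s` seconds and scaled to unit peak.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric vector of kernel values at `seq(0, duration_s, by = tr)`.
#' @export
#' @examples
#' h <- canonical_hrf(0.1)
#' which.max(h) # peak near 5 s
canonical_hrf <- function(tr, duration_s = 32) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("'tr' must be a positive finite scalar", call. = FALSE)
  }
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Regressor label sets for the two first-level schemes.
# two_run_gain_loss: 8 anticipation conditions (+/- 0/20/100/500 yen),
#   2 control events, 12 amount-specific feedback x outcome regressors and
#   one common feedback per +/-0 yen condition -> 24 condition regressors.
# one_run_gain: 4 gain anticipation conditions, 8 feedback x outcome
#   regressors (including 0 yen hit/miss), 2 control events -> 14.
scheme_conditions <- function(scheme) {
  amounts <- c(0L, 20L, 100L, 500L)
  switch(scheme,
    two_run_gain_loss = c(
      paste0("ant_gain_", amounts), paste0("ant_loss_", amounts),
      "neutral_cue", "neutral_feedback",
      as.vector(t(outer(
        c(paste0("fb_gain_", amounts[-1]), paste0("fb_loss_", amounts[-1])),
        c("hit", "miss"), paste, sep = "_"
      ))),
      "fb_gain_0", "fb_loss_0"
    ),
    one_run_gain = c(
      paste0("ant_gain_", amounts),
      "neutral_cue", "neutral_feedback",
      as.vector(t(outer(paste0("fb_gain_", amounts), c("hit", "miss"),
                        paste, sep = "_")))
    ),
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
}

#' Build a first-level MID design matrix
#'
#' HRF-convolves one boxcar regressor per condition present in the event
#' table, appends the six motion parameters (if given) and one intercept per
#' run. Convolution is carried out at a microtime resolution of
#' `tr / oversample` separately within each run, so activity does not bleed
#' across the run boundary of concatenated runs.
#'
#' @param design A `mid_design` object (see [make_mid_design()]) or a list
#'   with `events` (data.frame `onset_s`, `duration_s`, `condition`),
#'   `scheme`, and `run_start_s` (first-volume time of each run, seconds).
#' @param tr Repetition time in seconds.
#' @param n_vol Number of volumes in the series.
#' @param motion Optional `n_vol` x 6 motion-parameter matrix.
#' @param oversample Microtime bins per TR (default 16).
#' @return List with `X` (design matrix), `labels` (column labels) and
#'   `condition_cols` (indices of the condition columns).
#' @export
build_design_matrix <- function(design, tr, n_vol, motion = NULL,
                                oversample = 16L) {
  events <- as.data.frame(design$events)
  run_start <- design$run_start_s
  if (is.null(run_start)) run_start <- 0
  known <- scheme_conditions(design$scheme)
  conds <- unique(as.character(events$condition))
  bad <- setdiff(conds, known)
  if (length(bad)) {
    stop("unknown condition label(s) for scheme '", design$scheme, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) && any(events$onset_s < 0)) {
    stop("event onsets must be non-negative", call. = FALSE)
  }
  if (nrow(events) && any(events$onset_s >= n_vol * tr)) {
    stop("event onset beyond scan end (", n_vol * tr, " s)", call. = FALSE)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_vol) {
      stop("'motion' must have one row per volume", call. = FALSE)
    }
  }
  conds <- known[known %in% conds] # canonical ordering
  dt <- tr / oversample
  total_t <- n_vol * tr
  n_micro <- n_vol * oversample
  hrf <- canonical_hrf(dt)
  run_end <- c(run_start[-1], total_t)

  Xc <- matrix(0, n_vol, length(conds), dimnames = list(NULL, conds))
  vol_idx <- (seq_len(n_vol) - 1L) * oversample + 1L
  for (j in seq_along(conds)) {
    micro <- numeric(n_micro)
    ev <- events[events$condition == conds[j], , drop = FALSE]
    for (r in seq_along(run_start)) {
      in_run <- ev$onset_s >= run_start[r] & ev$onset_s < run_end[r]
      if (!any(in_run)) next
      seg0 <- floor(run_start[r] / dt) + 1
      seg1 <- min(n_micro, ceiling(run_end[r] / dt))
      box <- numeric(seg1 - seg0 + 1L)
      for (i in which(in_run)) {
        a <- floor(ev$onset_s[i] / dt) + 1L - seg0 + 1L
        b <- min(length(box),
                 ceiling((ev$onset_s[i] + max(ev$duration_s[i], dt)) / dt) - seg0 + 1L)
        box[a:b] <- box[a:b] + 1
      }
      conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(box)]
      micro[seg0:seg1] <- conv
    }
    Xc[, j] <- micro[vol_idx]
  }

  # run intercepts from volume timing
  run_of_vol <- findInterval((seq_len(n_vol) - 1) * tr, run_start)
  Xr <- sapply(seq_along(run_start), function(r) as.numeric(run_of_vol == r))
  Xr <- matrix(Xr, nrow = n_vol)
  colnames(Xr) <- paste0("run", seq_along(run_start), "_intercept")

  if (is.null(motion)) {
    X <- cbind(Xc, Xr)
  } else {
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(Xc, motion, Xr)
  }
  list(X = X, labels = colnames(X), condition_cols = seq_along(conds))
}

#' Fit a first-level GLM by ordinary least squares
#'
#' @param Y `T x p` matrix of BOLD series (one column per ROI or voxel).
#' @param X Design matrix (`T x q`) or the list returned by
#'   [build_design_matrix()].
#' @return A `mid_glm` object: `betas` (q x p, rownames = column labels),
#'   `residual_variance` (per column), `design_rank`.
#' @details Rank-deficient designs are solved with the minimum-norm
#'   (pseudoinverse) solution and a warning.
#' @export
fit_glm <- function(Y, X) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have equal rows", call. = FALSE)
  qx <- qr(X)
  r <- qx$rank
  if (nrow(X) <= r) {
    stop("more design rank (", r, ") than can be estimated from ",
         nrow(X), " volumes", call. = FALSE)
  }
  if (r < ncol(X)) {
    warning("design matrix is rank deficient (rank ", r, " < ", ncol(X),
            " columns); returning minimum-norm solution")
    B <- MASS::ginv(X) %*% Y
  } else {
    B <- qr.coef(qx, Y)
  }
  rownames(B) <- colnames(X)
  res <- Y - X %*% B
  structure(list(
    betas = B,
    residual_variance = colSums(res^2) / (nrow(X) - r),
    design_rank = r
  ), class = "mid_glm")
}

#' Gain-anticipation contrasts
#'
#' Each contrast is an "amount vs. 0 yen anticipation" difference of
#' parameter estimates; the average contrast weights the three amounts
#' equally (1/3 each) against the 0 yen condition, so it equals the mean of
#' the three pairwise contrasts by construction.
#'
#' @param glm A `mid_glm` object with anticipation betas
#'   `ant_gain_0/20/100/500`.
#' @return A `contrast_set` list with elements `small`, `medium`, `maximal`,
#'   `average` (each one value per ROI/voxel column).
#' @export
anticipation_contrasts <- function(glm) {
  stopifnot(inherits(glm, "mid_glm"))
  need <- paste0("ant_gain_", c(0, 20, 100, 500))
  missing <- setdiff(need, rownames(glm$betas))
  if (length(missing)) {
    stop("missing anticipation condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  b <- glm$betas[need, , drop = FALSE]
  nm <- colnames(b)
  small <- stats::setNames(b[2, ] - b[1, ], nm)
  medium <- stats::setNames(b[3, ] - b[1, ], nm)
  maximal <- stats::setNames(b[4, ] - b[1, ], nm)
  structure(list(
    small = small, medium = medium, maximal = maximal,
    average = (small + medium + maximal) / 3
  ), class = "contrast_set")
}

#' Mean value over merged sphere ROIs on a value grid
#'
#' Voxel membership is Euclidean distance (mm) at or below `radius_mm` from
#' any centre; bilateral/multiple spheres are unioned before averaging, so
#' overlapping voxels count once. An optional boolean mask (e.g. grey
#' matter) is intersected before averaging.
#'
#' @param values 3-D array of voxel values.
#' @param affine 4x4 voxel-index-to-mm affine; voxel indices are 0-based,
#'   i.e. `mm = affine %*% c(i - 1, j - 1, k - 1, 1)` for array index
#'   `(i, j, k)`.
#' @param centers_mm Matrix (or vector) of sphere centres, one row per
#'   centre, columns x/y/z in mm.
#' @param radius_mm Sphere radius in mm (boundary inclusive).
#' @param mask Optional logical array of the same dimension.
#' @return Mean of `values` over the merged ROI (single number).
#' @export
sphere_roi_values <- function(values, affine, centers_mm, radius_mm,
                              mask = NULL) {
  values <- as.array(values)
  dm <- dim(values)
  if (length(dm) != 3L) stop("'values' must be a 3-D array", call. = FALSE)
  centers_mm <- matrix(centers_mm, ncol = 3)
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  mm <- cbind(idx, 1) %*% t(affine)
  member <- rep(FALSE, nrow(mm))
  for (c in seq_len(nrow(centers_mm))) {
    d2 <- (mm[, 1] - centers_mm[c, 1])^2 + (mm[, 2] - centers_mm[c, 2])^2 +
      (mm[, 3] - centers_mm[c, 3])^2
    member <- member | (d2 <= radius_mm^2)
  }
  if (!is.null(mask)) member <- member & as.logical(mask)
  if (!any(member)) {
    stop("ROI is empty: no grid point within ", radius_mm,
         " mm of any centre", call. = FALSE)
  }
  mean(as.vector(values)[member])
}
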