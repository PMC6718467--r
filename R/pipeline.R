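#' Vectorise a connectivity matrix into edge features
#'
#' Strict upper triangle in row-major order: for ROIs 1..n the features are
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n); length n(n-1)/2. This
#' ordering is the fixed contract shared with [refold_weights()].
#'
#' @param matrix Symmetric matrix (asymmetry beyond `tol` is an error).
#' @param tol Largest tolerated asymmetry (default 1e-8).
#' @return Numeric vector of upper-triangle values.
#' @export
vectorize_fc <- function(matrix, tol = 1e-8) {
  M <- as.matrix(matrix)
  if (nrow(M) != ncol(M)) stop("matrix must be square", call. = FALSE)
  if (max(abs(M - t(M))) > tol) {
    stop("matrix is asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  t(M)[lower.tri(M)]
}

#' Estimation/held-out split with cohort-proportional allocation
#'
#' Allocates `n_holdout` subjects over the cohorts proportionally to cohort
#' size with largest-remainder rounding (ties to the smaller cohort index),
#' samples the held-out members within each cohort, and randomly assigns
#' the estimation subjects to `k` cross-validation folds whose sizes differ
#' by at most one (a warning is issued when they differ at all).
#'
#' @param subject_ids Character or integer subject identifiers.
#' @param cohort_labels Cohort of each subject (same length).
#' @param n_holdout Held-out sample size (default 15).
#' @param k Number of folds (default 10).
#' @param seed Optional RNG seed; the plan is deterministic per seed.
#' @return A `split_plan`: `estimation_ids`, `holdout_ids`, `fold` (named
#'   integer vector over estimation subjects), `k`, `seed`.
#' @export
make_split <- function(subject_ids, cohort_labels, n_holdout = 15, k = 10,
                       seed = NULL) {
  subject_ids <- as.character(subject_ids)
  stopifnot(length(subject_ids) == length(cohort_labels),
            !anyDuplicated(subject_ids))
  n <- length(subject_ids)
  if (n_holdout < 0 || n_holdout >= n) {
    stop("'n_holdout' must be in [0, n)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cohorts <- sort(unique(cohort_labels))
  sizes <- vapply(cohorts, function(cc) sum(cohort_labels == cc), integer(1))
  quota <- n_holdout * sizes / n
  take <- floor(quota)
  rem <- quota - take
  extra <- n_holdout - sum(take)
  if (extra > 0) {
    ord <- order(-rem, seq_along(cohorts))
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  if (any(take > sizes)) {
    stop("a cohort is smaller than its holdout quota", call. = FALSE)
  }
  holdout <- character(0)
  for (i in seq_along(cohorts)) {
    ids_c <- subject_ids[cohort_labels == cohorts[i]]
    if (take[i] > 0) holdout <- c(holdout, sample(ids_c, take[i]))
  }
  estimation <- setdiff(subject_ids, holdout)
  n_est <- length(estimation)
  if (k < 2 || k > n_est) stop("'k' must be in [2, n_estimation]", call. = FALSE)
  if (n_est %% k != 0) {
    warning("estimation size ", n_est, " not divisible by k = ", k,
            "; fold sizes differ by one")
  }
  fold <- sample(rep(seq_len(k), length.out = n_est))
  names(fold) <- estimation
  structure(list(estimation_ids = estimation, holdout_ids = holdout,
                 fold = fold, k = k, seed = seed),
            class = "split_plan")
}

# Pre-compute per-fold (and full-estimation) linear kernels so that
# permutation reruns, which permute targets only, do not rebuild them.
prepare_cv_kernels <- function(X_est, plan, center = TRUE) {
  ids <- plan$estimation_ids
  X_est <- X_est[ids, , drop = FALSE]
  folds <- lapply(seq_len(plan$k), function(f) {
    test <- ids[plan$fold[ids] == f]
    train <- setdiff(ids, test)
    Ktr <- build_kernel(X_est[train, , drop = FALSE], center = center)
    Kte <- build_kernel(X_est[train, , drop = FALSE],
                        X_est[test, , drop = FALSE],
                        center = center, xbar = attr(Ktr, "xbar"))
    list(train = train, test = test, K_train = Ktr, K_test = Kte,
         xbar = attr(Ktr, "xbar"))
  })
  K_full <- build_kernel(X_est, center = center)
  list(folds = folds, K_full = K_full, xbar_full = attr(K_full, "xbar"),
       ids = ids, X_est = X_est, center = center)
}

#' Cross-validated RVR over a split plan
#'
#' For every fold, fits an RVR model on the training subjects and scores
#' the held-out fold members, yielding concatenated out-of-fold raw scores
#' over the whole estimation set; additionally fits the model on the
#' complete estimation set. Per-fold and full-set primal weight vectors are
#' collected for the fold-averaged weight map.
#'
#' @param features `n x d` feature matrix with subject ids as rownames.
#' @param targets Named numeric vector of targets (estimation subjects).
#' @param plan A `split_plan`.
#' @param rvr_config List of arguments passed on to [rvr_fit()].
#' @param kernels Optional pre-computed kernel set (internal; from
#'   `prepare_cv_kernels`).
#' @param center Centre kernels with training means (default TRUE).
#' @param collect_weights Also compute primal weights (default TRUE).
#' @param fit_full Fit the complete-estimation-set model (default TRUE;
#'   implied by `collect_weights`).
#' @return List: `raw_oof` (named out-of-fold raw scores), `fold_weights`
#'   (k x d), `fold_biases`, `full_weights`, `full_bias`, `avg_w`,
#'   `avg_bias` (fold + full averages), `kernels`.
#' @export
run_cv <- function(features, targets, plan, rvr_config = list(),
                   kernels = NULL, center = TRUE, collect_weights = TRUE,
                   fit_full = TRUE) {
  if (is.null(kernels)) kernels <- prepare_cv_kernels(features, plan, center)
  ids <- kernels$ids
  targets <- targets[ids]
  if (anyNA(targets)) stop("targets missing for some estimation subjects",
                           call. = FALSE)
  d <- ncol(kernels$X_est)
  raw <- stats::setNames(rep(NA_real_, length(ids)), ids)
  Wf <- if (collect_weights) matrix(0, plan$k, d) else NULL
  bf <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    fd <- kernels$folds[[f]]
    y_tr <- targets[fd$train]
    if (stats::var(y_tr) == 0) {
      warning("fold ", f, " has zero target variance; fitting anyway")
    }
    m <- do.call(rvr_fit, c(list(K = fd$K_train, y = y_tr), rvr_config))
    raw[fd$test] <- rvr_predict(m, fd$K_test)
    if (collect_weights) {
      pw <- rvr_primal_weights(m, kernels$X_est[fd$train, , drop = FALSE],
                               xbar = fd$xbar)
      Wf[f, ] <- pw$w
      bf[f] <- pw$bias
    }
  }
  out <- list(raw_oof = raw, fold_biases = bf, kernels = kernels)
  if (!fit_full && !collect_weights) return(out)
  m_full <- do.call(rvr_fit,
                    c(list(K = kernels$K_full, y = targets), rvr_config))
  out$model_full <- m_full
  if (collect_weights) {
    pw_full <- rvr_primal_weights(m_full, kernels$X_est,
                                  xbar = kernels$xbar_full)
    out$fold_weights <- Wf
    out$full_weights <- pw_full$w
    out$full_bias <- pw_full$bias
    out$avg_w <- averaged_weights(Wf, pw_full$w)
    out$avg_bias <- mean(c(bf, pw_full$bias))
  }
  out
}

#' Fold-averaged weight vector
#'
#' Unweighted mean of the k per-fold primal weight vectors and the
#' complete-estimation-set weight vector (k + 1 terms).
#'
#' @param fold_weights `k x d` matrix of per-fold weights.
#' @param full_set_weights Length-d weight vector from the full estimation
#'   fit.
#' @return Length-d averaged weight vector.
#' @export
averaged_weights <- function(fold_weights, full_set_weights) {
  fold_weights <- as.matrix(fold_weights)
  if (ncol(fold_weights) != length(full_set_weights)) {
    stop("weight vector lengths differ", call. = FALSE)
  }
  colMeans(rbind(fold_weights, full_set_weights))
}

#' Scaling correction of raw model scores
#'
#' OLS regression of the actual values on the raw scores over the
#' estimation set; the returned affine map `intercept + slope * raw` is
#' applied to any raw score (estimation or held-out). Correlation with the
#' actual values is unchanged by the correction (affine invariance);
#' only the MSE is affected.
#'
#' @param raw_scores_est Raw scores on the estimation set.
#' @param actual_est Actual target values (same order).
#' @return List with `intercept` and `slope`.
#' @export
scaling_correction <- function(raw_scores_est, actual_est) {
  if (length(raw_scores_est) != length(actual_est) ||
      length(raw_scores_est) < 3) {
    stop("need >= 3 paired estimation scores", call. = FALSE)
  }
  if (stats::var(raw_scores_est) == 0) {
    stop("raw scores are constant; scaling regression is undefined",
         call. = FALSE)
  }
  cf <- stats::lm.fit(cbind(1, raw_scores_est), actual_est)$coefficients
  list(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' @rdname scaling_correction
#' @param scaling A scaling-correction list.
#' @param raw Raw scores to correct.
#' @export
apply_scaling <- function(scaling, raw) {
  scaling$intercept + scaling$slope * raw
}

#' Pearson correlation and mean squared error of predictions
#'
#' @param predicted,actual Equal-length numeric vectors (>= 3 values).
#' @return List with `r` (NA with a warning when either side has zero
#'   variance) and `mse`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) < 3) {
    stop("need >= 3 paired values", call. = FALSE)
  }
  mse <- mean((predicted - actual)^2)
  if (stats::var(predicted) == 0 || stats::var(actual) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, mse = mse))
  }
  list(r = stats::cor(predicted, actual), mse = mse)
}

#' Permutation significance of cross-validated prediction performance
#'
#' Permutes the targets across the estimation subjects, reruns the full
#' cross-validation (same fold structure), scaling correction and
#' evaluation for each permutation, and reports
#' `p = (1 + #\{perm r >= observed r\}) / (1 + n_perm)` for the correlation
#' and the analogous left-tail count for the MSE. When `holdout` data are
#' supplied, a complete-estimation-set model is refitted per permutation
#' and the held-out statistics are put through the same counting formula.
#'
#' @param features Estimation-set feature matrix (rownames = subject ids).
#' @param targets Named target vector for the estimation subjects.
#' @param plan A `split_plan`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional RNG seed.
#' @param rvr_config Arguments for [rvr_fit()].
#' @param center Kernel centering flag.
#' @param kernels Optional pre-computed kernels.
#' @param holdout Optional list with `features` and `targets` of the
#'   held-out subjects.
#' @return List: `p_r`, `p_mse`, `observed` (list `r`, `mse`), `perm_r`,
#'   `perm_mse`; with holdout also `p_r_holdout`, `p_mse_holdout`,
#'   `observed_holdout`.
#' @export
permutation_significance <- function(features, targets, plan, n_perm,
                                     seed = NULL, rvr_config = list(),
                                     center = TRUE, kernels = NULL,
                                     holdout = NULL) {
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  if (is.null(kernels)) kernels <- prepare_cv_kernels(features, plan, center)
  ids <- kernels$ids
  y <- targets[ids]
  if (!is.null(seed)) set.seed(seed)

  eval_cv <- function(y_perm, with_holdout) {
    names(y_perm) <- ids
    cv <- run_cv(NULL, y_perm, plan, rvr_config, kernels = kernels,
                 collect_weights = with_holdout, fit_full = with_holdout)
    sc <- scaling_correction(cv$raw_oof, y_perm)
    est <- evaluate_predictions(apply_scaling(sc, cv$raw_oof), y_perm)
    out <- list(est = est)
    if (with_holdout) {
      raw_est <- drop(features[ids, , drop = FALSE] %*% cv$avg_w) + cv$avg_bias
      raw_hold <- drop(holdout$features %*% cv$avg_w) + cv$avg_bias
      sc_h <- scaling_correction(raw_est, y_perm)
      out$hold <- evaluate_predictions(apply_scaling(sc_h, raw_hold),
                                       holdout$targets)
    }
    out
  }

  with_hold <- !is.null(holdout)
  obs <- eval_cv(y, with_hold)
  perm_r <- perm_mse <- numeric(n_perm)
  perm_rh <- perm_mseh <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    yp <- sample(y)
    ev <- eval_cv(yp, with_hold)
    perm_r[p] <- ev$est$r
    perm_mse[p] <- ev$est$mse
    if (with_hold) {
      perm_rh[p] <- ev$hold$r
      perm_mseh[p] <- ev$hold$mse
    }
  }
  count_ge <- function(x, o) (1 + sum(!is.na(x) & x >= o)) / (1 + n_perm)
  count_le <- function(x, o) (1 + sum(!is.na(x) & x <= o)) / (1 + n_perm)
  out <- list(
    p_r = count_ge(perm_r, obs$est$r),
    p_mse = count_le(perm_mse, obs$est$mse),
    observed = obs$est, perm_r = perm_r, perm_mse = perm_mse
  )
  if (with_hold) {
    out$p_r_holdout <- count_ge(perm_rh, obs$hold$r)
    out$p_mse_holdout <- count_le(perm_mseh, obs$hold$mse)
    out$observed_holdout <- obs$hold
  }
  out
}

#' Full prediction analysis for the three VS measures
#'
#' Runs the complete pipeline on a (synthetic or ingested) cohort: clean
#' each subject's resting series with the combined nuisance model, compute
#' Pearson FC and vectorise it; obtain per-subject VS measures either from
#' the first-level task GLM (`measure_source = "glm"`) or from the stored
#' simulation truth (`"true"`); split into estimation and held-out samples
#' stratified by cohort; per measure run 10-fold cross-validated RVR,
#' average the fold and full-set primal weights, fit the scaling
#' correction on the estimation set, evaluate estimation (out-of-fold) and
#' held-out performance, and optionally attach permutation p-values.
#'
#' Held-out subjects never enter kernel centering, fold models or the
#' scaling regression.
#'
#' @param cohort A cohort object (see [simulate_cohort()]) or a list with
#'   `subjects` and `roi_set`.
#' @param config Named list overriding any of: `n_holdout` (15), `k` (10),
#'   `n_perm` (0), `seed` (1), `measure_source` ("glm" or "true"),
#'   `n_pcs` (3), `f_lo` (0.01), `f_hi` (0.1), `center_kernel` (TRUE),
#'   `rvr` (list of [rvr_fit()] arguments).
#' @return A `vs_prediction` object: `measures` (per-measure result lists),
#'   `features`, `targets`, `plan`, `config`. Each per-measure result
#'   holds `predictions` (data.frame id/set/raw/corrected/actual),
#'   `r_train`, `mse_train`, `r_holdout`, `mse_holdout`, `scaling_oof`,
#'   `scaling_holdout`, `averaged_weight_vector`, and permutation
#'   p-values when `n_perm > 0`.
#' @export
run_full_analysis <- function(cohort, config = list()) {
  cfg <- utils::modifyList(list(
    n_holdout = 15, k = 10, n_perm = 0, seed = 1,
    measure_source = "glm", n_pcs = 3, f_lo = 0.01, f_hi = 0.1,
    center_kernel = TRUE, rvr = list()
  ), config)

  features <- cohort_features(cohort, n_pcs = cfg$n_pcs,
                              f_lo = cfg$f_lo, f_hi = cfg$f_hi)
  targets <- cohort_targets(cohort, source = cfg$measure_source)
  ids <- rownames(features)
  cohorts <- vapply(cohort$subjects, function(s) s$cohort, numeric(1))
  plan <- make_split(ids, cohorts, n_holdout = cfg$n_holdout, k = cfg$k,
                     seed = cfg$seed)
  est <- plan$estimation_ids
  hold <- plan$holdout_ids
  X_est <- features[est, , drop = FALSE]
  X_hold <- features[hold, , drop = FALSE]
  kernels <- prepare_cv_kernels(X_est, plan, center = cfg$center_kernel)

  res <- list()
  for (meas in c("sensitivity", "maximal", "average")) {
    y <- stats::setNames(targets[, meas], rownames(targets))
    y_est <- y[est]
    cv <- run_cv(NULL, y_est, plan, cfg$rvr, kernels = kernels)

    sc_oof <- scaling_correction(cv$raw_oof, y_est)
    corr_oof <- apply_scaling(sc_oof, cv$raw_oof)
    ev_est <- evaluate_predictions(corr_oof, y_est)

    raw_avg_est <- drop(X_est %*% cv$avg_w) + cv$avg_bias
    sc_hold <- scaling_correction(raw_avg_est, y_est)
    raw_hold <- drop(X_hold %*% cv$avg_w) + cv$avg_bias
    corr_hold <- apply_scaling(sc_hold, raw_hold)
    ev_hold <- evaluate_predictions(corr_hold, y[hold])

    out <- list(
      predictions = rbind(
        data.frame(subject_id = est, set = "estimation",
                   raw = unname(cv$raw_oof), corrected = unname(corr_oof),
                   actual = unname(y_est)),
        data.frame(subject_id = hold, set = "holdout",
                   raw = unname(raw_hold), corrected = unname(corr_hold),
                   actual = unname(y[hold]))
      ),
      r_train = ev_est$r, mse_train = ev_est$mse,
      r_holdout = ev_hold$r, mse_holdout = ev_hold$mse,
      scaling_oof = sc_oof, scaling_holdout = sc_hold,
      averaged_weight_vector = cv$avg_w, avg_bias = cv$avg_bias
    )
    if (cfg$n_perm > 0) {
      ps <- permutation_significance(
        X_est, y_est, plan, n_perm = cfg$n_perm,
        seed = cfg$seed + 1000L, rvr_config = cfg$rvr,
        center = cfg$center_kernel, kernels = kernels,
        holdout = list(features = X_hold, targets = y[hold])
      )
      out$p_r <- ps$p_r
      out$p_mse <- ps$p_mse
      out$p_r_holdout <- ps$p_r_holdout
      out$p_mse_holdout <- ps$p_mse_holdout
    }
    res[[meas]] <- out
  }
  structure(list(measures = res, features = features, targets = targets,
                 plan = plan, config = cfg),
            class = "vs_prediction")
}

#' Per-subject edge features from cleaned resting data
#'
#' @param cohort Cohort object.
#' @param n_pcs Tissue PCs per compartment.
#' @param f_lo,f_hi Passband edges (Hz).
#' @return `n_subjects x n_edges` matrix, rownames = subject ids.
#' @export
cohort_features <- function(cohort, n_pcs = 3, f_lo = 0.01, f_hi = 0.1) {
  rows <- lapply(cohort$subjects, function(s) {
    N <- nuisance_model(nrow(s$rest_ts), s$tr_rest, motion = s$motion,
                        wm = s$wm_signals, csf = s$csf_signals,
                        n_pcs = n_pcs, f_lo = f_lo, f_hi = f_hi)
    vectorize_fc(fc_matrix(clean_timeseries(s$rest_ts, N)))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort$subjects, function(s) s$subject_id,
                        character(1))
  X
}

#' Per-subject VS measures (GLM-derived or simulation truth)
#'
#' @param cohort Cohort object.
#' @param source `"glm"` (fit the first-level model on the task series) or
#'   `"true"` (use the stored generative targets).
#' @return Matrix with columns sensitivity/maximal/average, rownames =
#'   subject ids.
#' @export
cohort_targets <- function(cohort, source = c("glm", "true")) {
  source <- match.arg(source)
  rows <- lapply(cohort$subjects, function(s) {
    if (source == "true") {
      m <- s$targets_true
    } else {
      if (is.null(s$task_ts)) {
        stop("subject ", s$subject_id, " has no task series; use ",
             "measure_source = 'true' or simulate the task", call. = FALSE)
      }
      X <- build_design_matrix(s$design, s$tr_task, nrow(s$task_ts),
                               motion = s$task_motion)
      m <- vs_measures(anticipation_contrasts(fit_glm(s$task_ts, X)))
    }
    c(sensitivity = m$sensitivity, maximal = m$maximal, average = m$average)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(cohort$subjects, function(s) s$subject_id,
                          character(1))
  out
}
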