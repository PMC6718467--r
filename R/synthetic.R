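#' Build a desk-scale ROI set with network labels
#'
#' ROIs are assigned contiguously to the seven functional networks plus
#' basal ganglia and cerebellum (VI, SM, DA, VA, FT, FP, DM, BG, CB) and
#' given coordinates sampled uniformly inside an MNI-like bounding box
#' (x within c(-70, 70), y within c(-105, 70), z within c(-45, 75) mm),
#' rounded to whole millimetres.
#'
#' @param n_roi Number of ROIs (>= 2).
#' @param networks Optional named integer vector of ROI counts per network
#'   (names from the nine labels, summing to `n_roi`). By default the
#'   ROIs are spread over all nine networks roughly proportionally to
#'   typical parcellation shares (DM largest).
#' @param radius_mm Sphere radius stored with the set (default 6).
#' @param seed Optional RNG seed; output is deterministic per seed.
#' @return A `roi_set`: `n_roi`, `coordinates` (n x 3, columns x/y/z),
#'   `radius_mm`, `network_label`.
#' @export
make_roi_set <- function(n_roi, networks = NULL, radius_mm = 6,
                         seed = NULL) {
  if (n_roi < 2) stop("'n_roi' must be at least 2", call. = FALSE)
  lv <- network_levels()
  if (is.null(networks)) {
    share <- c(VI = 3, SM = 3, DA = 2, VA = 2, FT = 1.5, FP = 2.5,
               DM = 4, BG = 1, CB = 1)
    quota <- n_roi * share / sum(share)
    networks <- floor(quota)
    rem <- n_roi - sum(networks)
    if (rem > 0) {
      ord <- order(-(quota - networks), seq_along(quota))
      networks[ord[seq_len(rem)]] <- networks[ord[seq_len(rem)]] + 1
    }
  } else {
    if (!all(names(networks) %in% lv)) {
      stop("network names must be among: ", paste(lv, collapse = ", "),
           call. = FALSE)
    }
    if (sum(networks) != n_roi) {
      stop("network counts must sum to n_roi", call. = FALSE)
    }
    networks <- networks[intersect(lv, names(networks))]
  }
  if (!is.null(seed)) set.seed(seed)
  label <- rep(names(networks), times = networks)
  coords <- cbind(
    x = round(stats::runif(n_roi, -70, 70)),
    y = round(stats::runif(n_roi, -105, 70)),
    z = round(stats::runif(n_roi, -45, 75))
  )
  structure(list(n_roi = as.integer(n_roi), coordinates = coords,
                 radius_mm = radius_mm, network_label = label),
            class = "roi_set")
}

#' Block-structured resting covariance over labelled networks
#'
#' Correlation matrix with `within_net_r` inside network blocks and
#' `between_net_r` elsewhere (unit diagonal). `within_net_r` may be a
#' single value or a named per-network vector, and `between_net_r` a
#' single value or a named symmetric network-by-network matrix — which is
#' how subject-level within- and between-network coupling variation is
#' injected. If the raw block matrix is not positive definite it is
#' repaired by clipping eigenvalues at a small positive floor and
#' rescaling to unit diagonal; the repair is recorded in the `repaired`
#' attribute.
#'
#' @param roi_set A `roi_set` (its `network_label` defines the blocks).
#' @param within_net_r Within-network correlation(s), each in (-1, 1).
#' @param between_net_r Between-network correlation — scalar (must not
#'   exceed any within-network value) or a named symmetric matrix of
#'   per-network-pair values.
#' @return Positive-definite correlation matrix.
#' @export
make_rest_cov <- function(roi_set, within_net_r = 0.5, between_net_r = 0.1) {
  lab <- roi_set$network_label
  n <- roi_set$n_roi
  nets <- unique(lab)
  if (length(within_net_r) == 1L && is.null(names(within_net_r))) {
    within <- stats::setNames(rep(within_net_r, length(nets)), nets)
  } else {
    within <- within_net_r
    if (!all(nets %in% names(within))) {
      stop("'within_net_r' must name every network in the ROI set",
           call. = FALSE)
    }
  }
  if (is.matrix(between_net_r)) {
    if (!all(nets %in% rownames(between_net_r)) ||
        !all(nets %in% colnames(between_net_r))) {
      stop("'between_net_r' matrix must name every network", call. = FALSE)
    }
    between <- between_net_r
  } else {
    if (between_net_r > min(within)) {
      stop("'between_net_r' must not exceed any within-network correlation",
           call. = FALSE)
    }
    between <- matrix(between_net_r, length(nets), length(nets),
                      dimnames = list(nets, nets))
  }
  if (any(abs(within) >= 1) || any(abs(between) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  C <- matrix(0, n, n)
  for (a in nets) {
    for (b in nets) {
      C[lab == a, lab == b] <- between[a, b]
    }
  }
  for (net in nets) {
    idx <- which(lab == net)
    C[idx, idx] <- within[[net]]
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) <= 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    C <- ev$vectors %*% (vals * t(ev$vectors))
    C <- stats::cov2cor(C)
    repaired <- TRUE
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("covariance not positive definite after repair", call. = FALSE)
    }
  }
  attr(C, "repaired") <- repaired
  C
}

# smooth low-rank factor scores used for tissue signals
ar1_factors <- function(n_vol, k, ar = 0.5) {
  F <- matrix(stats::rnorm(n_vol * k, sd = sqrt(1 - ar^2)), n_vol, k)
  apply(F, 2, function(x) stats::filter(x, ar, method = "recursive"))
}

#' Simulate resting ROI series with recorded confounds
#'
#' ROI innovations are multivariate Gaussian with covariance `cov`,
#' temporally filtered to lag-1 autocorrelation `ar_coef` (innovations are
#' scaled so the stationary marginal covariance stays `cov`; correlations
#' are unaffected by the common AR filter). Six motion parameters are
#' smooth random walks; WM and CSF signal matrices are exact rank-3
#' factor products so that three principal components capture them
#' completely. Motion and tissue factors are mixed linearly into the ROI
#' series with recorded coefficients, which makes the combined nuisance
#' regression removable to numerical precision.
#'
#' @param cov Positive-definite ROI covariance.
#' @param n_vol Number of volumes (>= 20).
#' @param tr Repetition time (s).
#' @param ar_coef Lag-1 autocorrelation, |ar_coef| < 1 (default 0.3).
#' @param seed Optional RNG seed.
#' @param confound_strength Scale of the mixing coefficients (default 0.3;
#'   0 disables contamination).
#' @param n_tissue_cols Columns per tissue signal matrix (default 8).
#' @return List: `ts` (observed series), `latent` (pre-contamination
#'   series), `motion` (n_vol x 6), `wm_signals`, `csf_signals`
#'   (n_vol x `n_tissue_cols`, rank 3), `mixing` (recorded coefficients).
#' @export
simulate_rest_ts <- function(cov, n_vol, tr, ar_coef = 0.3, seed = NULL,
                             confound_strength = 0.3, n_tissue_cols = 8) {
  if (n_vol < 20) stop("'n_vol' must be at least 20", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("|ar_coef| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cov)
  R <- tryCatch(chol(cov), error = function(e) {
    stop("covariance is not positive definite", call. = FALSE)
  })
  E <- matrix(stats::rnorm(n_vol * n), n_vol, n) %*% R
  if (ar_coef != 0) {
    E <- E * sqrt(1 - ar_coef^2)
    Y <- apply(E, 2, function(x) {
      stats::filter(x, ar_coef, method = "recursive")
    })
  } else {
    Y <- E
  }
  Y <- matrix(as.numeric(Y), n_vol, n)

  motion <- apply(matrix(stats::rnorm(n_vol * 6, sd = 0.05), n_vol, 6),
                  2, cumsum)
  F_wm <- ar1_factors(n_vol, 3)
  F_csf <- ar1_factors(n_vol, 3)
  L_wm <- matrix(stats::rnorm(3 * n_tissue_cols), 3, n_tissue_cols)
  L_csf <- matrix(stats::rnorm(3 * n_tissue_cols), 3, n_tissue_cols)
  wm <- F_wm %*% L_wm
  csf <- F_csf %*% L_csf

  B_motion <- matrix(stats::rnorm(6 * n, sd = confound_strength), 6, n)
  B_wm <- matrix(stats::rnorm(3 * n, sd = confound_strength), 3, n)
  B_csf <- matrix(stats::rnorm(3 * n, sd = confound_strength), 3, n)
  ts <- Y + motion %*% B_motion + F_wm %*% B_wm + F_csf %*% B_csf

  list(ts = ts, latent = Y, motion = motion, wm_signals = wm,
       csf_signals = csf,
       mixing = list(motion = B_motion, wm = B_wm, csf = B_csf,
                     wm_factors = F_wm, csf_factors = F_csf))
}

#' Generate a pseudo-randomised MID trial design
#'
#' `two_run_gain_loss`: two concatenated runs of 90 trials each — 40 gain
#' (10 per amount 0/20/100/500 yen), 40 loss (same amounts) and 10 neutral
#' trials in shuffled order. `one_run_gain`: a single run of 62 win trials
#' (spread as evenly as possible over the four amounts: 16/16/15/15) plus
#' 18 neutral trials. (The source protocol describes the single-run
#' variant as "90 trials" although its stated condition counts sum to 80;
#' the generator follows the explicit 62 + 18 counts.) Each trial is cue,
#' jittered anticipation interval, target and feedback; hits are Bernoulli
#' with the staircase-calibrated rate 0.66. Anticipation regressor epochs
#' span cue onset to target onset.
#'
#' The protocol gives no per-event second timings; the defaults (cue
#' 0.5 s, anticipation uniformly jittered 2–2.5 s, target window 0.5 s,
#' feedback 1.65 s) are configurable stand-ins.
#'
#' @param scheme `"two_run_gain_loss"` or `"one_run_gain"`.
#' @param seed Optional RNG seed.
#' @param timing List with `cue`, `ant_range` (length 2), `target`,
#'   `feedback` (seconds).
#' @param hit_rate Probability of a hit (default 0.66).
#' @return A `mid_design`: `events` (data.frame `onset_s`, `duration_s`,
#'   `condition`), `trials` (per-trial table), `scheme`, `run_start_s`,
#'   `duration_s`.
#' @export
make_mid_design <- function(scheme = c("two_run_gain_loss", "one_run_gain"),
                            seed = NULL,
                            timing = list(cue = 0.5, ant_range = c(2, 2.5),
                                          target = 0.5, feedback = 1.65),
                            hit_rate = 0.66) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  amounts <- c(0L, 20L, 100L, 500L)
  one_run_trials <- function() {
    if (scheme == "two_run_gain_loss") {
      data.frame(
        type = c(rep("gain", 40), rep("loss", 40), rep("neutral", 10)),
        amount = c(rep(amounts, each = 10), rep(amounts, each = 10),
                   rep(NA_integer_, 10))
      )
    } else {
      data.frame(
        type = c(rep("gain", 62), rep("neutral", 18)),
        amount = c(rep(amounts, times = c(16, 16, 15, 15)),
                   rep(NA_integer_, 18))
      )
    }
  }
  n_runs <- if (scheme == "two_run_gain_loss") 2L else 1L
  run_start <- numeric(n_runs)
  events <- list()
  trials <- list()
  t <- 0
  for (r in seq_len(n_runs)) {
    run_start[r] <- t
    tr_tab <- one_run_trials()
    tr_tab <- tr_tab[sample(nrow(tr_tab)), , drop = FALSE]
    tr_tab$run <- r
    tr_tab$hit <- stats::runif(nrow(tr_tab)) < hit_rate
    for (i in seq_len(nrow(tr_tab))) {
      ant <- stats::runif(1, timing$ant_range[1], timing$ant_range[2])
      epoch <- timing$cue + ant
      ty <- tr_tab$type[i]
      am <- tr_tab$amount[i]
      if (ty == "neutral") {
        cue_cond <- "neutral_cue"
        fb_cond <- "neutral_feedback"
      } else {
        cue_cond <- paste0("ant_", ty, "_", am)
        fb_cond <- if (am == 0L) {
          if (scheme == "one_run_gain") {
            paste0("fb_", ty, "_0_", if (tr_tab$hit[i]) "hit" else "miss")
          } else {
            paste0("fb_", ty, "_0") # common hit/miss feedback for +/-0 yen
          }
        } else {
          paste0("fb_", ty, "_", am, "_",
                 if (tr_tab$hit[i]) "hit" else "miss")
        }
      }
      fb_on <- t + epoch + timing$target
      events[[length(events) + 1L]] <- data.frame(
        onset_s = c(t, fb_on),
        duration_s = c(epoch, timing$feedback),
        condition = c(cue_cond, fb_cond)
      )
      tr_tab$onset_s[i] <- t
      t <- fb_on + timing$feedback
    }
    trials[[r]] <- tr_tab
    t <- ceiling(t / 10) * 10 # pad to a round run boundary
  }
  structure(list(
    events = do.call(rbind, events),
    trials = do.call(rbind, trials),
    scheme = scheme,
    run_start_s = run_start,
    duration_s = t
  ), class = "mid_design")
}

#' Simulate task BOLD series from a design and true condition amplitudes
#'
#' `series = X_cond %*% beta + noise`, where `X_cond` holds the
#' HRF-convolved condition columns from [build_design_matrix()] (the same
#' builder the GLM uses, so a noiseless simulate-then-fit round trip is
#' exact). Conditions absent from `true_task_betas` get amplitude zero.
#'
#' @param design A `mid_design`.
#' @param true_task_betas Named amplitude vector (names = condition
#'   labels) or a conditions x series matrix.
#' @param tr Repetition time (s).
#' @param n_vol Number of volumes; default covers the design plus 20 s.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Optional RNG seed.
#' @return `n_vol x n_series` matrix of BOLD values.
#' @export
simulate_task_ts <- function(design, true_task_betas, tr, n_vol = NULL,
                             noise_sd = 0, seed = NULL) {
  if (is.null(n_vol)) n_vol <- ceiling((design$duration_s + 20) / tr)
  dm <- build_design_matrix(design, tr, n_vol)
  Xc <- dm$X[, dm$condition_cols, drop = FALSE]
  if (is.null(dim(true_task_betas))) {
    true_task_betas <- matrix(true_task_betas,
                              dimnames = list(names(true_task_betas), NULL))
  }
  B <- matrix(0, ncol(Xc), ncol(true_task_betas))
  hit <- intersect(colnames(Xc), rownames(true_task_betas))
  B[match(hit, colnames(Xc)), ] <- true_task_betas[hit, ]
  Y <- Xc %*% B
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y))
  }
  Y
}

# row-major strict-upper-triangle index of edge (i, j), i < j
edge_index <- function(i, j, n_roi) {
  stopifnot(all(i < j))
  (i - 1) * n_roi - i * (i - 1) / 2 + (j - i)
}

#' Sparse ground-truth edge weights for the three VS targets
#'
#' The sensitivity and maximal-reward weight patterns share most of their
#' support (edges inside the `support_network` block), mirroring the
#' strong empirical correlation between those two measures; the
#' average-reward pattern mixes the shared block with edges between the
#' support network and the VA network. All other edges carry weight zero.
#' By default the support covers the whole network block — contributions
#' that are coherent at network level, which is the level at which the
#' weight-matrix decomposition reads them out.
#'
#' @param roi_set A `roi_set`.
#' @param n_support Number of within-block support edges per pattern;
#'   `NULL` (default) uses every edge inside the support network.
#' @param support_network Network whose within-block edges carry the
#'   shared pattern (default "DM").
#' @param noise_sd_target Target noise level as a multiple of each
#'   noiseless predictor's standard deviation (default 1; 0 = noise-free).
#' @param null_weights All-zero weights (targets become pure noise).
#' @param seed Optional RNG seed.
#' @return A `ground_truth` list: `true_edge_weights` (d x 3 matrix,
#'   columns sensitivity/maximal/average), `noise_sd_target`,
#'   `support_edges`.
#' @export
make_ground_truth <- function(roi_set, n_support = NULL,
                              support_network = "DM", noise_sd_target = 1,
                              null_weights = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- roi_set$n_roi
  d <- n * (n - 1) / 2
  W <- matrix(0, d, 3,
              dimnames = list(NULL, c("sensitivity", "maximal", "average")))
  support <- list()
  if (!null_weights) {
    lab <- roi_set$network_label
    in_net <- which(lab == support_network)
    if (length(in_net) < 2) {
      stop("support network '", support_network, "' has fewer than 2 ROIs",
           call. = FALSE)
    }
    pairs <- t(utils::combn(in_net, 2))
    idx_within <- edge_index(pairs[, 1], pairs[, 2], n)
    base_idx <- if (!is.null(n_support) && length(idx_within) > n_support) {
      sample(idx_within, n_support)
    } else idx_within
    base_w <- stats::rnorm(length(base_idx), mean = 1, sd = 0.3)

    va <- which(lab == "VA")
    cross <- integer(0)
    if (length(va) >= 1) {
      cp <- expand.grid(a = in_net, b = va)
      cross_all <- edge_index(pmin(cp$a, cp$b), pmax(cp$a, cp$b), n)
      cross <- sample(cross_all, min(10, length(cross_all)))
    }
    W[base_idx, "sensitivity"] <- base_w
    W[base_idx, "maximal"] <- 0.85 * base_w +
      stats::rnorm(length(base_idx), sd = 0.15)
    W[base_idx, "average"] <- 0.45 * base_w
    if (length(cross)) {
      W[cross, "average"] <- stats::rnorm(length(cross), mean = 0.7,
                                          sd = 0.15)
    }
    support <- list(base = base_idx, cross = cross)
  }
  structure(list(true_edge_weights = W, noise_sd_target = noise_sd_target,
                 support_edges = support),
            class = "ground_truth")
}

#' Link VS targets to functional-connectivity features
#'
#' Each target is the inner product of the subject's edge features with
#' the corresponding true weight vector, plus Gaussian noise whose
#' standard deviation is `noise_sd_target` times the noiseless predictor's
#' across-subject standard deviation (an absolute unit scale is used when
#' the predictor is degenerate, e.g. under all-zero weights).
#'
#' @param fc_features `n_subjects x d` edge-feature matrix.
#' @param ground_truth A `ground_truth` object.
#' @param seed Optional RNG seed.
#' @return `n_subjects x 3` target matrix (sensitivity/maximal/average).
#' @export
link_targets <- function(fc_features, ground_truth, seed = NULL) {
  F <- as.matrix(fc_features)
  W <- ground_truth$true_edge_weights
  if (ncol(F) != nrow(W)) {
    stop("feature length ", ncol(F), " does not match the ", nrow(W),
         " true edge weights", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  signal <- F %*% W
  noise_mult <- ground_truth$noise_sd_target
  out <- signal
  for (j in seq_len(ncol(W))) {
    s <- stats::sd(signal[, j])
    base <- if (is.finite(s) && s > 0) s else 1
    if (noise_mult > 0) {
      out[, j] <- signal[, j] +
        stats::rnorm(nrow(F), sd = noise_mult * base)
    }
  }
  rownames(out) <- rownames(F)
  out
}

#' Simulate a complete multi-site cohort with recorded ground truth
#'
#' Generates a cohort mirroring the three-site study layout: 14/15/16
#' subjects with site-specific resting acquisitions (TR 2.5/2.0/2.7 s and
#' 120/143/107 volumes after trimming) and MID schemes (two gain/loss
#' runs for sites 1 and 3, one gain-only run for site 2; task TR 2 s).
#' Each subject gets a site-level block covariance perturbed by recorded
#' per-network coupling jitter, resting series with injected motion and
#' rank-3 tissue confounds, a pseudo-randomised task design, and a VS task
#' series whose anticipation amplitudes are constructed so the first-level
#' contrasts reproduce the linked targets exactly at zero noise. Targets
#' are linked to the subject's *cleaned* FC features (same nuisance model
#' the analysis applies), so the mapping is recoverable by the pipeline.
#'
#' @param config Named list overriding defaults: `n_per_cohort`
#'   (c(14, 15, 16)), `n_roi` (40), `networks`, `within_net_r` (0.5),
#'   `between_net_r` (0.1), `coupling_sd` (0.2; subject-level jitter of
#'   each network's within-block correlation), `between_sd` (0.1;
#'   subject-level jitter of each network-pair coupling),
#'   `ar_coef` (0.3), `rest_tr` (c(2.5, 2, 2.7)), `rest_vols`
#'   (c(120, 143, 107)), `task_tr` (2), `schemes`, `noise_sd_task` (0.5),
#'   `noise_sd_target` (1), `n_support` (15), `support_network` ("DM"),
#'   `n_support` (NULL = all within-block edges), `null_weights` (FALSE),
#'   `simulate_task` (TRUE), `baseline_beta`
#'   (0.2), `confound_strength` (0.3), `target_scale` (noiseless-predictor
#'   standard deviations per measure, in VS contrast units: 0.3/0.8/1.0),
#'   `n_pcs` (3), `f_lo`/`f_hi` (0.01/0.1).
#' @param seed RNG seed; the whole cohort is deterministic per seed.
#' @return A `vs_cohort`: `subjects` (list of subject records), `roi_set`,
#'   `ground_truth` (with `linking_features` and `targets` recorded),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_per_cohort = c(14, 15, 16), n_roi = 40, networks = NULL,
    within_net_r = 0.5, between_net_r = 0.1,
    coupling_sd = 0.2, between_sd = 0.1, ar_coef = 0.3,
    rest_tr = c(2.5, 2.0, 2.7), rest_vols = c(120, 143, 107),
    task_tr = 2.0,
    schemes = c("two_run_gain_loss", "one_run_gain", "two_run_gain_loss"),
    noise_sd_task = 0.5, noise_sd_target = 1,
    n_support = NULL, support_network = "DM", null_weights = FALSE,
    simulate_task = TRUE, baseline_beta = 0.2, confound_strength = 0.3,
    target_scale = c(sensitivity = 0.3, maximal = 0.8, average = 1.0),
    n_pcs = 3, f_lo = 0.01, f_hi = 0.1
  ), config)
  set.seed(seed)
  roi_set <- make_roi_set(cfg$n_roi, networks = cfg$networks)
  gt <- make_ground_truth(roi_set, n_support = cfg$n_support,
                          support_network = cfg$support_network,
                          noise_sd_target = cfg$noise_sd_target,
                          null_weights = cfg$null_weights)
  nets <- unique(roi_set$network_label)
  n_coh <- length(cfg$n_per_cohort)

  subjects <- list()
  feats <- list()
  sid <- 0
  for (cc in seq_len(n_coh)) {
    for (s in seq_len(cfg$n_per_cohort[cc])) {
      sid <- sid + 1
      coupling <- stats::setNames(
        pmin(pmax(cfg$within_net_r +
                    stats::rnorm(length(nets), sd = cfg$coupling_sd),
                  cfg$between_net_r + 0.05), 0.95),
        nets)
      # per-network-pair between coupling: individual differences live at
      # the level of specific network pairs, not one global offset
      nn <- length(nets)
      btw <- matrix(0, nn, nn, dimnames = list(nets, nets))
      jit <- stats::rnorm(nn * (nn - 1) / 2, sd = cfg$between_sd)
      btw[upper.tri(btw)] <- cfg$between_net_r + jit
      btw <- btw + t(btw)
      cap <- outer(coupling, coupling, pmin) - 0.03
      btw <- pmin(pmax(btw, -0.3), cap)
      cov_s <- make_rest_cov(roi_set, within_net_r = coupling,
                             between_net_r = btw)
      rest <- simulate_rest_ts(cov_s, cfg$rest_vols[cc], cfg$rest_tr[cc],
                               ar_coef = cfg$ar_coef,
                               confound_strength = cfg$confound_strength)
      N <- nuisance_model(cfg$rest_vols[cc], cfg$rest_tr[cc],
                          motion = rest$motion, wm = rest$wm_signals,
                          csf = rest$csf_signals, n_pcs = cfg$n_pcs,
                          f_lo = cfg$f_lo, f_hi = cfg$f_hi)
      feats[[sid]] <- vectorize_fc(fc_matrix(clean_timeseries(rest$ts, N)))
      subjects[[sid]] <- list(
        subject_id = sprintf("sub%02d", sid), cohort = cc,
        rest_ts = rest$ts, tr_rest = cfg$rest_tr[cc],
        motion = rest$motion, wm_signals = rest$wm_signals,
        csf_signals = rest$csf_signals, rest_mixing = rest$mixing,
        coupling = coupling, between_coupling = btw,
        tr_task = cfg$task_tr
      )
    }
  }
  features <- do.call(rbind, feats)
  rownames(features) <- vapply(subjects, `[[`, character(1), "subject_id")
  if (!cfg$null_weights) {
    # put the three measures on realistic VS contrast-unit scales
    # (slope < maximal < average), a unit choice that leaves r untouched
    signal_sd <- apply(features %*% gt$true_edge_weights, 2, stats::sd)
    ok <- is.finite(signal_sd) & signal_sd > 0
    gt$true_edge_weights[, ok] <- sweep(
      gt$true_edge_weights[, ok, drop = FALSE], 2,
      cfg$target_scale[ok] / signal_sd[ok], "*")
  }
  targets <- link_targets(features, gt)

  for (i in seq_along(subjects)) {
    tg <- targets[i, ]
    subjects[[i]]$targets_true <- list(
      sensitivity = unname(tg["sensitivity"]),
      maximal = unname(tg["maximal"]),
      average = unname(tg["average"])
    )
    if (cfg$simulate_task) {
      cc <- subjects[[i]]$cohort
      scheme <- cfg$schemes[cc]
      design <- make_mid_design(scheme)
      # anticipation amplitudes that make the GLM contrasts reproduce the
      # targets: c_max = maximal, c_small = maximal - 2*sensitivity,
      # c_med = 3*average - 2*maximal + 2*sensitivity
      c3 <- tg["maximal"]
      c1 <- c3 - 2 * tg["sensitivity"]
      c2 <- 3 * tg["average"] - 2 * c3 + 2 * tg["sensitivity"]
      b0 <- cfg$baseline_beta
      other <- setdiff(scheme_conditions(scheme),
                       paste0("ant_gain_", c(0, 20, 100, 500)))
      betas <- c(
        stats::setNames(c(b0, b0 + c1, b0 + c2, b0 + c3),
                        paste0("ant_gain_", c(0, 20, 100, 500))),
        stats::setNames(stats::rnorm(length(other), 0.3, 0.1), other)
      )
      n_vol <- ceiling((design$duration_s + 20) / cfg$task_tr)
      ts <- simulate_task_ts(design, betas, cfg$task_tr, n_vol,
                             noise_sd = 0)
      task_motion <- apply(matrix(stats::rnorm(n_vol * 6, sd = 0.05),
                                  n_vol, 6), 2, cumsum)
      B_tm <- matrix(stats::rnorm(6, sd = 0.1), 6, 1)
      ts <- ts + task_motion %*% B_tm
      if (cfg$noise_sd_task > 0) {
        ts <- ts + matrix(stats::rnorm(length(ts),
                                       sd = cfg$noise_sd_task), nrow(ts))
      }
      subjects[[i]]$design <- design
      subjects[[i]]$task_ts <- ts
      subjects[[i]]$task_motion <- task_motion
      subjects[[i]]$true_task_betas <- betas
    }
  }
  gt$linking_features <- features
  gt$targets <- targets
  structure(list(subjects = subjects, roi_set = roi_set, ground_truth = gt,
                 config = cfg, seed = seed),
            class = "vs_cohort")
}
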