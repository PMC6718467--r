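#' Rank-slope model of reward sensitivity
#'
#' Fits the linear model `value = b0 + b1 * rank` by ordinary least squares
#' to the three gain-anticipation contrast values at ranks 1 (=20 yen),
#' 2 (=100 yen) and 3 (=500 yen). The slope `b1` is the reward-sensitivity
#' parameter: a larger slope means a steeper increase of VS activation with
#' reward magnitude rank. Rank, not yen amount, is the regressor because VS
#' activation is closer to linear in rank; fitting against the raw amounts
#' is available via `ranks` for sensitivity analyses.
#'
#' @param values Numeric vector of length 3: contrast values at ranks 1..3
#'   (small, medium, maximal).
#' @param ranks Regressor values (default `1:3`).
#' @return List with `b0` (intercept) and `b1` (slope).
#' @export
#' @examples
#' fit_rank_slope(c(0.2, 0.5, 0.8)) # b1 = 0.3
fit_rank_slope <- function(values, ranks = 1:3) {
  if (length(values) != 3L || anyNA(values)) {
    stop("'values' must be the 3 contrast values at ranks 1, 2, 3",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, ranks), values)
  list(b0 = unname(fit$coefficients[1]), b1 = unname(fit$coefficients[2]))
}

#' The three VS prediction targets from a contrast set
#'
#' `sensitivity` is the rank slope over the small/medium/maximal contrasts,
#' `maximal` the 500-vs-0 yen contrast, `average` the mean-gain contrast.
#' Vectorised over ROIs/voxels (each contrast may be a vector).
#'
#' @param contrasts A `contrast_set` (see [anticipation_contrasts()]).
#' @return A `vs_measures` list: `sensitivity`, `maximal`, `average`,
#'   `intercept` (the rank-model constant term b0).
#' @export
vs_measures <- function(contrasts) {
  stopifnot(inherits(contrasts, "contrast_set"))
  v <- rbind(contrasts$small, contrasts$medium, contrasts$maximal)
  if (anyNA(v)) stop("contrast set contains missing values", call. = FALSE)
  # closed form of the rank-1..3 OLS line, identical to fit_rank_slope()
  b1 <- (v[3, ] - v[1, ]) / 2
  b0 <- colMeans(v) - 2 * b1
  structure(list(
    sensitivity = unname(b1),
    maximal = unname(contrasts$maximal),
    average = unname(contrasts$average),
    intercept = unname(b0)
  ), class = "vs_measures")
}
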