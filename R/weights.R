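#' Refold an edge-space weight vector into an ROI x ROI matrix
#'
#' Inverse of [vectorize_fc()]: symmetric placement of the strict
#' upper-triangle (row-major) values, zero diagonal.
#'
#' @param weight_vector Length `n_roi (n_roi - 1) / 2` vector.
#' @param n_roi Number of ROIs.
#' @return Symmetric `n_roi x n_roi` matrix with zero diagonal.
#' @export
refold_weights <- function(weight_vector, n_roi) {
  d <- n_roi * (n_roi - 1) / 2
  if (length(weight_vector) != d) {
    stop("weight vector has length ", length(weight_vector),
         "; expected ", d, " for ", n_roi, " ROIs", call. = FALSE)
  }
  W <- matrix(0, n_roi, n_roi)
  W[lower.tri(W)] <- weight_vector # row-major upper triangle of t(W)
  W <- t(W)
  W + t(W)
}

#' Top-k nodes by weight sum
#'
#' Node score is the sum of |weight| (or signed weight) over the node's
#' incident edges; nodes are reported in descending score order with ties
#' broken by ROI index for reproducibility.
#'
#' @param W Weight matrix (symmetric, zero diagonal).
#' @param roi_set Optional `roi_set` providing network labels and
#'   coordinates.
#' @param k Number of nodes to report (default 5; truncated with a warning
#'   when `k > n_roi`).
#' @param signed Use signed instead of absolute weights (default FALSE).
#' @return data.frame: roi, network (if available), x/y/z (if available),
#'   score.
#' @export
rank_nodes <- function(W, roi_set = NULL, k = 5, signed = FALSE) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n, " ROIs; truncating")
    k <- n
  }
  score <- rowSums(if (signed) W else abs(W))
  ord <- order(-score, seq_len(n))[seq_len(k)]
  out <- data.frame(roi = ord, score = score[ord])
  if (!is.null(roi_set)) {
    out$network <- roi_set$network_label[ord]
    out <- cbind(out[, "roi", drop = FALSE],
                 roi_set$coordinates[ord, , drop = FALSE],
                 network = roi_set$network_label[ord],
                 score = score[ord])
  }
  rownames(out) <- NULL
  out
}

#' Top-k edges by absolute weight
#'
#' Each undirected edge is listed once; the signed weight is reported while
#' the ranking uses the absolute value, ties broken by edge position.
#'
#' @param W Weight matrix.
#' @param roi_set Optional `roi_set` for labels/coordinates.
#' @param k Number of edges (default 5; truncated to the edge count).
#' @return data.frame: roi_i, roi_j, (networks/coordinates if available),
#'   weight.
#' @export
rank_edges <- function(W, roi_set = NULL, k = 5) {
  W <- as.matrix(W)
  n <- nrow(W)
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  # match the row-major feature ordering
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  w <- W[pairs]
  k <- min(k, nrow(pairs))
  ord <- order(-abs(w), seq_along(w))[seq_len(k)]
  out <- data.frame(roi_i = pairs[ord, 1], roi_j = pairs[ord, 2],
                    weight = w[ord])
  if (!is.null(roi_set)) {
    ci <- roi_set$coordinates[out$roi_i, , drop = FALSE]
    cj <- roi_set$coordinates[out$roi_j, , drop = FALSE]
    colnames(ci) <- paste0(c("x", "y", "z"), "_i")
    colnames(cj) <- paste0(c("x", "y", "z"), "_j")
    out <- cbind(out[, c("roi_i", "roi_j")], ci,
                 network_i = roi_set$network_label[out$roi_i], cj,
                 network_j = roi_set$network_label[out$roi_j],
                 weight = out$weight)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate edge weights by functional network
#'
#' Cell (A, B) is the mean |weight| (or signed weight) over all edges with
#' one endpoint in network A and the other in B; the diagonal aggregates
#' the unordered ROI pairs inside a network. Networks follow the fixed
#' order VI, SM, DA, VA, FT, FP, DM, BG, CB (seven functional networks
#' plus basal ganglia and cerebellum); networks without any edge yield NA.
#'
#' @param W Weight matrix.
#' @param network_labels Network label per ROI.
#' @param signed Aggregate signed weights (default FALSE = absolute).
#' @return Symmetric 9 x 9 (or `n_networks` squared) matrix.
#' @export
network_aggregate <- function(W, network_labels, signed = FALSE) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (length(network_labels) != n || anyNA(network_labels)) {
    stop("every ROI needs exactly one network label", call. = FALSE)
  }
  lv <- network_levels()
  extra <- setdiff(unique(as.character(network_labels)), lv)
  lv <- c(lv, extra)
  lab <- factor(as.character(network_labels), levels = lv)
  vals <- if (signed) W else abs(W)
  nn <- length(lv)
  agg <- matrix(NA_real_, nn, nn, dimnames = list(lv, lv))
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  a <- as.integer(lab[pairs[, 1]])
  b <- as.integer(lab[pairs[, 2]])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  w <- vals[pairs]
  for (i in seq_len(nn)) {
    for (j in i:nn) {
      sel <- lo == i & hi == j
      if (any(sel)) agg[i, j] <- agg[j, i] <- mean(w[sel])
    }
  }
  agg
}

# canonical network ordering shared by the generator and the aggregator
network_levels <- function() {
  c("VI", "SM", "DA", "VA", "FT", "FP", "DM", "BG", "CB")
}
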