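#' Write a matrix as tab-delimited text
#'
#' @param x Matrix or data.frame.
#' @param path Output file.
#' @param col_names Write a header row (default TRUE when column names
#'   exist).
#' @export
write_matrix_tsv <- function(x, path, col_names = !is.null(colnames(x))) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col_names)
  invisible(path)
}

#' Read a delimited-text time-series matrix
#'
#' @param path File with one column per ROI/signal (tab- or
#'   comma-delimited, header optional and auto-detected).
#' @return Numeric matrix.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  probe <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(probe)))
  as.matrix(utils::read.table(path, sep = sep, header = header))
}

#' Read an event table (onset_s, duration_s, condition)
#'
#' @param path Delimited-text file with columns `onset_s`, `duration_s`,
#'   `condition`.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(ev))) {
    stop("event table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ev
}

#' Read an ROI coordinate table (roi_id, x, y, z, network)
#'
#' @param path Delimited-text table.
#' @param radius_mm Sphere radius to attach (default 6).
#' @return A `roi_set`.
#' @export
read_roi_table <- function(path, radius_mm = 6) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  structure(list(
    n_roi = nrow(tab),
    coordinates = as.matrix(tab[, c("x", "y", "z")]),
    radius_mm = radius_mm,
    network_label = as.character(tab$network)
  ), class = "roi_set")
}

#' Write a synthetic cohort as delimited text plus JSON ground truth
#'
#' Writes per-subject rest/motion/WM/CSF/task series and event tables, a
#' cohort manifest, the ROI table and the ground-truth weights.
#'
#' @param cohort A `vs_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- cohort$roi_set
  write_matrix_tsv(data.frame(roi_id = seq_len(rs$n_roi),
                              rs$coordinates,
                              network = rs$network_label),
                   file.path(dir, "roi_table.tsv"))
  man <- list()
  for (s in cohort$subjects) {
    id <- s$subject_id
    write_matrix_tsv(s$rest_ts, file.path(dir, paste0(id, "_rest.tsv")),
                     col_names = FALSE)
    write_matrix_tsv(s$motion, file.path(dir, paste0(id, "_motion.tsv")),
                     col_names = FALSE)
    write_matrix_tsv(s$wm_signals, file.path(dir, paste0(id, "_wm.tsv")),
                     col_names = FALSE)
    write_matrix_tsv(s$csf_signals, file.path(dir, paste0(id, "_csf.tsv")),
                     col_names = FALSE)
    if (!is.null(s$task_ts)) {
      write_matrix_tsv(s$task_ts, file.path(dir, paste0(id, "_task.tsv")),
                       col_names = FALSE)
      write_matrix_tsv(s$design$events,
                       file.path(dir, paste0(id, "_events.tsv")))
    }
    man[[length(man) + 1L]] <- data.frame(
      subject_id = id, cohort = s$cohort, tr_rest = s$tr_rest,
      tr_task = if (is.null(s$tr_task)) NA else s$tr_task,
      rest_path = paste0(id, "_rest.tsv"),
      sensitivity_true = s$targets_true$sensitivity,
      maximal_true = s$targets_true$maximal,
      average_true = s$targets_true$average
    )
  }
  manifest <- file.path(dir, "manifest.tsv")
  write_matrix_tsv(do.call(rbind, man), manifest)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(true_edge_weights = gt$true_edge_weights,
         noise_sd_target = gt$noise_sd_target,
         support_edges = gt$support_edges,
         seed = cohort$seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, matrix = "columnmajor"
  )
  invisible(manifest)
}

#' Write an FC matrix as square text plus an edge list
#'
#' @param fc Symmetric connectivity matrix.
#' @param prefix Path prefix; writes `<prefix>_matrix.tsv` and
#'   `<prefix>_edges.tsv` (roi_i, roi_j, r).
#' @export
write_fc <- function(fc, prefix) {
  write_matrix_tsv(fc, paste0(prefix, "_matrix.tsv"), col_names = FALSE)
  pairs <- which(upper.tri(fc), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  write_matrix_tsv(data.frame(roi_i = pairs[, 1], roi_j = pairs[, 2],
                              r = fc[pairs]),
                   paste0(prefix, "_edges.tsv"))
  invisible(prefix)
}

#' Write prediction results: per-subject tables, metrics JSON and weights
#'
#' @param result A `vs_prediction` from [run_full_analysis()].
#' @param dir Output directory.
#' @export
write_prediction_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list()
  for (meas in names(result$measures)) {
    m <- result$measures[[meas]]
    write_matrix_tsv(m$predictions,
                     file.path(dir, paste0("predictions_", meas, ".tsv")))
    write_matrix_tsv(
      data.frame(edge = seq_along(m$averaged_weight_vector),
                 weight = m$averaged_weight_vector),
      file.path(dir, paste0("weights_", meas, ".tsv"))
    )
    metrics[[meas]] <- m[intersect(
      c("r_train", "mse_train", "r_holdout", "mse_holdout",
        "p_r", "p_mse", "p_r_holdout", "p_mse_holdout"),
      names(m))]
  }
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
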