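# Transient-level and cell-type metrics, and method comparison.

#' Match predicted activity against ground-truth transients
#'
#' A real transient counts as detected if the prediction exceeds the
#' threshold on at least one frame of its inclusive `[onset, peak]` rise.
#' Predicted transients are the maximal supra-threshold runs; a predicted
#' transient is true if it intersects at least one real rise. A predicted
#' run spanning two real transients counts once in the prediction tally but
#' marks both reals detected.
#'
#' @param ground_truth a `cacti_labels` (or a two-column interval matrix for
#'   a single cell).
#' @param prediction a `cacti_predictions`, a probability matrix, or a
#'   numeric vector for a single cell.
#' @param threshold activation threshold; "active" means probability
#'   strictly greater than this (default 0.5).
#' @return `cacti_match`: counts `n_real`, `n_real_detected`, `n_predicted`,
#'   `n_predicted_true`, plus per-transient `rise_coverage` fractions.
#' @export
match_transients <- function(ground_truth, prediction, threshold = 0.5) {
  gt_list <- if (inherits(ground_truth, "cacti_labels")) ground_truth$intervals
    else list(ground_truth)
  prob <- if (inherits(prediction, "cacti_predictions")) prediction$prob
    else if (is.matrix(prediction)) prediction else matrix(prediction, nrow = 1)
  if (length(gt_list) != nrow(prob))
    stop_config("match_transients: %d cells in truth vs %d prediction rows",
                length(gt_list), nrow(prob))
  nf <- if (inherits(ground_truth, "cacti_labels")) ground_truth$n_frames
    else ncol(prob)
  if (ncol(prob) != nf)
    stop_config("match_transients: %d frames in truth vs %d in prediction",
                nf, ncol(prob))
  tot <- list(n_real = 0L, n_real_detected = 0L, n_predicted = 0L,
              n_predicted_true = 0L, rise_coverage = numeric(0))
  for (i in seq_along(gt_list)) {
    gt <- gt_list[[i]]
    if (is.null(gt)) gt <- matrix(integer(0), ncol = 2)
    active <- prob[i, ] > threshold
    pred <- raster_to_labels(matrix(active, nrow = 1))$intervals[[1]]
    tot$n_real <- tot$n_real + nrow(gt)
    tot$n_predicted <- tot$n_predicted + nrow(pred)
    for (k in seq_len(nrow(gt))) {
      fr <- (gt[k, 1]:gt[k, 2]) + 1L
      cov <- mean(active[fr])
      tot$rise_coverage <- c(tot$rise_coverage, cov)
      if (any(active[fr])) tot$n_real_detected <- tot$n_real_detected + 1L
    }
    for (k in seq_len(nrow(pred))) {
      if (nrow(gt) && any(intervals_intersect(gt[, 1], gt[, 2],
                                              pred[k, 1], pred[k, 2])))
        tot$n_predicted_true <- tot$n_predicted_true + 1L
    }
  }
  structure(tot, class = "cacti_match")
}

#' Per-transient rise coverage
#'
#' For each real transient, the fraction of its rise-time frames
#' (`[onset, peak]`, inclusive) on which the prediction is above threshold.
#'
#' @inheritParams match_transients
#' @return numeric vector, one fraction per real transient.
#' @export
rise_coverage <- function(ground_truth, prediction, threshold = 0.5) {
  match_transients(ground_truth, prediction, threshold)$rise_coverage
}

#' Sensitivity, precision and F1 from a transient match
#'
#' Sensitivity is the proportion of real transients detected; precision the
#' proportion of detected transients that are real; F1 their harmonic mean.
#' Empty denominators yield `NA` (absent), never 0.
#'
#' @param match a `cacti_match`.
#' @return list with `sensitivity`, `precision`, `f1`.
#' @export
metric_report <- function(match) {
  sens <- if (match$n_real > 0) match$n_real_detected / match$n_real else NA_real_
  prec <- if (match$n_predicted > 0)
    match$n_predicted_true / match$n_predicted else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else if (!is.na(sens) && !is.na(prec)) 0
    else NA_real_
  list(sensitivity = sens, precision = prec, f1 = f1)
}

#' @export
print.cacti_match <- function(x, ...) {
  r <- metric_report(x)
  cat(sprintf(paste0("<cacti_match> %d real (%d detected), %d predicted ",
                     "(%d true)\n  sensitivity %.3f  precision %.3f  F1 %.3f\n"),
              x$n_real, x$n_real_detected, x$n_predicted, x$n_predicted_true,
              r$sensitivity, r$precision, r$f1))
  invisible(x)
}

#' Per-class metrics from a cell-type confusion matrix
#'
#' Rows are predicted classes, columns ground-truth classes. Sensitivity is
#' `diag / column sum`, precision `diag / row sum`, micro-F1
#' `trace / total`. Zero rows or columns give `NA` for that class.
#'
#' @param confusion square integer matrix (predicted x truth).
#' @return list with per-class `sensitivity`, `precision`, `f1`, plus
#'   `micro_f1` and support-weighted `weighted_f1`.
#' @export
celltype_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop_config("celltype_metrics: confusion matrix must be square")
  if (any(confusion < 0) || sum(confusion) == 0)
    stop_config("celltype_metrics: invalid confusion matrix")
  dg <- diag(confusion)
  col_s <- colSums(confusion); row_s <- rowSums(confusion)
  sens <- ifelse(col_s > 0, dg / col_s, NA_real_)
  prec <- ifelse(row_s > 0, dg / row_s, NA_real_)
  f1 <- ifelse(!is.na(sens) & !is.na(prec) & (sens + prec) > 0,
               2 * sens * prec / (sens + prec), NA_real_)
  support <- col_s / sum(confusion)
  list(sensitivity = sens, precision = prec, f1 = f1,
       micro_f1 = sum(dg) / sum(confusion),
       weighted_f1 = sum(f1 * support, na.rm = TRUE))
}

#' Compare two methods' per-cell scores with a Wilcoxon signed-rank test
#'
#' Paired two-sided test at an a priori 0.05 level; only run on
#' distributions with more than `min_n` samples (default 15), refusing
#' otherwise. Pairs with zero difference carry no signed rank; if all pairs
#' are identical the test is undefined and refused.
#'
#' @param scores_a,scores_b paired per-cell scores (e.g. F1 values).
#' @param min_n minimal number of pairs (strictly greater than).
#' @return list with `statistic`, `p_value`, `n`, and significance `stars`
#'   (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise).
#' @export
compare_methods <- function(scores_a, scores_b, min_n = 15) {
  if (length(scores_a) != length(scores_b))
    stop_config("compare_methods: unpaired inputs")
  n <- length(scores_a)
  if (n <= min_n)
    stop_config(paste0("compare_methods: the signed-rank comparison is only",
                       " performed on distributions with >%d samples (got %d)"),
                min_n, n)
  if (all(scores_a == scores_b))
    stop_config("compare_methods: all pairs identical; no signed ranks")
  wt <- stats::wilcox.test(scores_a, scores_b, paired = TRUE)
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
    else "ns"
  list(statistic = unname(wt$statistic), p_value = p, n = n, stars = stars)
}

#' Adapt an external spike raster to transient-level detection
#'
#' Treats any third-party inference (e.g. an MCMC spike raster) as having
#' detected a transient if at least one spike falls within its rise time,
#' so external outputs can be scored with [metric_report()].
#'
#' @param ground_truth a `cacti_labels`.
#' @param spikes logical/0-1 matrix `n_cells x n_frames` of inferred spikes.
#' @return a `cacti_match` (predicted transients = maximal spike runs).
#' @export
match_spike_raster <- function(ground_truth, spikes) {
  match_transients(ground_truth, (spikes > 0) * 1, threshold = 0.5)
}
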