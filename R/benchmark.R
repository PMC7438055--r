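# Desk-scale end-to-end benchmark: simulate -> label -> stratify -> train ->
# predict -> evaluate -> overlap audit, entirely on simulator output.

#' Collect labeled patch samples for a set of cells
#'
#' Builds the stride-`stride` segment grid for each cell, classifies every
#' segment (REAL / FAKE_ONLY / EMPTY) against ground truth and putative
#' transients, and materializes the masked three-stream patches.
#'
#' @param movie a `cacti_movie`.
#' @param labels ground-truth `cacti_labels`.
#' @param putative putative-transient `cacti_labels`.
#' @param cells cell ids to include.
#' @param seq_len,window,stride pipeline geometry.
#' @return list with `segments` (data frame cell_id/start/class) and a
#'   closure `build(i)` materializing sample `i`.
#' @export
collect_segments <- function(movie, labels, putative, cells, seq_len = 100,
                             window = 25, stride = 10) {
  nf <- dim(movie$frames)[1]
  starts <- temporal_segments(nf, seq_len, stride)
  seg <- expand.grid(start = starts, cell_id = cells)[, c("cell_id", "start")]
  seg$class <- vapply(seq_len(nrow(seg)), function(k)
    classify_segment(labels, putative, seg$cell_id[k], seg$start[k], seq_len),
    character(1))
  build <- function(k) {
    s <- make_streams(movie, movie$cell_map, seg$cell_id[k], seg$start[k],
                      seq_len = seq_len, window = window, labels = labels)
    s
  }
  list(segments = seg, build = build)
}

# Ground-truth false transients: putative rises that do not intersect any
# true interval of their cell (extended by `slack` frames).
ground_truth_false_transients <- function(putative, labels, slack = 2) {
  out <- NULL
  for (i in seq_along(putative$cell_ids)) {
    id <- putative$cell_ids[i]
    pt <- putative$intervals[[i]]
    gt <- labels$intervals[[match(id, labels$cell_ids)]]
    for (k in seq_len(nrow(pt))) {
      hit <- nrow(gt) && any(intervals_intersect(gt[, 1] - slack,
                                                 gt[, 2] + slack,
                                                 pt[k, 1], pt[k, 2]))
      if (!hit)
        out <- rbind(out, data.frame(cell_id = id, onset = pt[k, 1],
                                     peak = pt[k, 2]))
    }
  }
  out %||% data.frame(cell_id = integer(0), onset = integer(0),
                      peak = integer(0))
}

#' Desk-scale training benchmark on simulated data
#'
#' Simulates an overlap-rich movie with well-separated transients, splits
#' cells into train/validation/test (no cell appears on two sides), builds
#' and stratifies the training pool, trains a small activity model on CPU,
#' and evaluates transient-level F1 on the held-out cells plus the fraction
#' of overlap-induced false transients the classifier rejects.
#'
#' @param seed master seed.
#' @param n_frames simulated movie length (default 2000).
#' @param n_cells number of simulated cells (default 16).
#' @param amp_meanlog,amp_sdlog amplitude distribution of the benchmark
#'   movie; defaults put virtually all transients above 5x the noise SD.
#' @param n_train_segments stratified training-pool size.
#' @param n_val_segments monitoring-pool size.
#' @param epochs,batch_size,lr training settings.
#' @param config model configuration (defaults to the desk preset).
#' @param shuffle_labels permute the training label vectors across samples
#'   (leakage guard: scores should collapse).
#' @param verbose print progress.
#' @return list with `fit`, `report` (held-out transient metrics), `audit`
#'   (overlap rejection), `predictions`, and the split.
#' @export
desk_benchmark <- function(seed = 1L, n_frames = 2000, n_cells = 16,
                           amp_meanlog = log(2.5), amp_sdlog = 0.2,
                           n_train_segments = 240, n_val_segments = 40,
                           epochs = 10, batch_size = 4, lr = 6e-3,
                           config = activity_model_config(preset = "desk"),
                           shuffle_labels = FALSE, verbose = FALSE) {
  sim <- simulate_movie(n_frames = n_frames, n_cells = n_cells,
                        amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
                        seed = seed)
  labels <- movie_labels(sim)
  putative <- detect_putative_transients_movie(sim)
  ids <- labels$cell_ids
  sp <- split_train_validation(rep(ids, 2), ratio = 0.8, seed = seed + 7L)
  test_cells <- sp$val_cells
  sp2 <- split_train_validation(rep(sp$train_cells, 2), ratio = 0.8,
                                seed = seed + 8L)
  train_cells <- sp2$train_cells; val_cells <- sp2$val_cells
  if (verbose)
    message(sprintf("cells: %d train / %d val / %d test",
                    length(train_cells), length(val_cells),
                    length(test_cells)))
  col <- collect_segments(sim, labels, putative, train_cells,
                          seq_len = config$seq_len, window = config$window)
  strat <- stratify(col$segments$class, n_out = n_train_segments,
                    seed = seed + 9L)
  train_samples <- lapply(strat$index, col$build)
  for (k in seq_along(train_samples)) train_samples[[k]]$weight <- strat$weight[k]
  vcol <- collect_segments(sim, labels, putative, val_cells,
                           seq_len = config$seq_len, window = config$window)
  vsel <- with_seed(seed + 10L,
                    sample.int(nrow(vcol$segments),
                               min(n_val_segments, nrow(vcol$segments))))
  val_samples <- lapply(vsel, vcol$build)
  if (shuffle_labels) {
    perm <- with_seed(seed + 11L, sample.int(length(train_samples)))
    lab <- lapply(train_samples, `[[`, "label")
    for (k in seq_along(train_samples))
      train_samples[[k]]$label <- lab[[perm[k]]]
  }
  model <- build_model(config, seed = seed + 12L)
  fit <- cacti_train(model, train_samples, val_samples = val_samples,
                     epochs = epochs, batch_size = batch_size, lr = lr,
                     augment_flags = strat$augment, seed = seed + 13L,
                     verbose = verbose)
  preds <- predict_movie(fit$model, sim)
  test_rows <- match(test_cells, preds$cell_ids)
  test_labels <- new_labels(labels$intervals[match(test_cells, labels$cell_ids)],
                            test_cells, labels$n_frames)
  report <- metric_report(match_transients(
    test_labels, preds$prob[test_rows, , drop = FALSE]))
  false_tr <- ground_truth_false_transients(putative, labels)
  audit <- audit_classifier(false_tr, preds)
  list(fit = fit, report = report, audit = audit, predictions = preds,
       movie = sim, labels = labels, putative = putative,
       split = list(train = train_cells, val = val_cells, test = test_cells),
       false_transients = false_tr)
}
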