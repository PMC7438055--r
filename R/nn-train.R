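# Training loop (RMSprop on weighted cross-entropy), movie-level inference,
# and the fitted-model object.

stream_names <- c("stream_cell", "stream_overlap", "stream_neuropil")

# Stack a list of cacti_patch into per-stream arrays [B, T, w, w].
stack_samples <- function(samples, cfg, augment_flags = NULL) {
  B <- length(samples)
  T <- cfg$seq_len; w <- cfg$window
  xs <- lapply(seq_len(cfg$n_streams), function(s)
    array(0, dim = c(B, T, w, w)))
  for (b in seq_len(B)) {
    sm <- samples[[b]]
    if (!is.null(augment_flags) && isTRUE(augment_flags[b]))
      sm <- random_augment(sm)
    for (s in seq_len(cfg$n_streams))
      xs[[s]][b, , , ] <- sm[[stream_names[s]]]
  }
  xs
}

random_augment <- function(sample) {
  op <- sample(c("flip_h", "flip_v", "rot90", "translate"), 1)
  tryCatch(switch(op,
    rot90 = augment_spatial(sample, "rot90", k = sample(1:3, 1)),
    translate = augment_spatial(sample, "translate",
                                dx = sample(-3:3, 1), dy = sample(-3:3, 1)),
    augment_spatial(sample, op)),
    error = function(e) sample)   # e.g. translation pushing the cell out
}

# Transient-level F1 of per-frame predictions over labeled samples.
samples_f1 <- function(prob, samples, threshold = 0.5) {
  tot <- list(n_real = 0L, n_real_detected = 0L, n_predicted = 0L,
              n_predicted_true = 0L, rise_coverage = numeric(0))
  for (b in seq_along(samples)) {
    y <- samples[[b]]$label
    gt <- raster_to_labels(matrix(y > 0.5, nrow = 1))$intervals[[1]]
    m <- match_transients(gt, prob[b, , drop = FALSE], threshold)
    for (f in c("n_real", "n_real_detected", "n_predicted",
                "n_predicted_true"))
      tot[[f]] <- tot[[f]] + m[[f]]
  }
  metric_report(structure(tot, class = "cacti_match"))
}

#' Train a classifier
#'
#' RMSprop on (weighted, per-frame) binary cross-entropy for the activity
#' model, or categorical cross-entropy for the cell-type model. Training is
#' deterministic given `seed` (weight updates, shuffling, dropout and online
#' augmentation all derive from it). Samples flagged for augmentation get a
#' fresh random spatial transform each epoch. Validation metrics are
#' computed at the end of each epoch; the reported best epoch maximizes test
#' F1 when a test set is supplied, validation F1 otherwise.
#'
#' @param model a `cacti_model` from [build_model()].
#' @param train_samples list of `cacti_patch` with `label` vectors (activity)
#'   or `class_label` integers (cell type) and `weight`s.
#' @param val_samples,test_samples optional labeled sample lists.
#' @param epochs number of passes over the training pool.
#' @param batch_size minibatch size.
#' @param lr learning rate (default from the model config).
#' @param augment_flags logical vector marking replicate samples to
#'   re-augment online each epoch.
#' @param seed integer seed controlling all randomness of the run.
#' @param verbose print per-epoch progress.
#' @return a `cacti_fit`: the model at the selected epoch, the per-epoch
#'   `history` data frame and the selection metadata.
#' @export
cacti_train <- function(model, train_samples, val_samples = NULL,
                        test_samples = NULL, epochs = 4, batch_size = 8,
                        lr = NULL, augment_flags = NULL, seed = 1L,
                        verbose = FALSE) {
  if (length(train_samples) == 0) stop_config("train: empty training set")
  cfg <- model$config
  lr <- lr %||% cfg$lr
  celltype <- !is.null(cfg$n_classes)
  n <- length(train_samples)
  state <- NULL
  history <- NULL
  best <- list(metric = -Inf, epoch = 1L, params = model$params)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batch <- 0
      for (start in seq(1, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, n)]
        B <- length(sel)
        xs <- stack_samples(train_samples[sel], cfg, augment_flags[sel])
        wts <- vapply(train_samples[sel], function(s) s$weight %||% 1,
                      numeric(1))
        fwd <- model_forward(model, xs, train = TRUE)
        if (!celltype) {
          y <- do.call(rbind, lapply(train_samples[sel], `[[`, "label"))
          p <- pmin(pmax(fwd$prob, 1e-7), 1 - 1e-7)
          loss <- -mean(sweep(y * log(p) + (1 - y) * log(1 - p), 1, wts, `*`))
          dl <- sweep(fwd$prob - y, 1, wts, `*`) / (B * cfg$seq_len)
          dlogits <- matrix(as.vector(dl), ncol = 1)
        } else {
          yi <- vapply(train_samples[sel], `[[`, numeric(1), "class_label")
          Y <- matrix(0, B, cfg$n_classes)
          Y[cbind(seq_len(B), yi)] <- 1
          p <- pmin(pmax(fwd$prob, 1e-7), 1)
          loss <- -mean(rowSums(Y * log(p)) * wts)
          dlogits <- sweep(fwd$prob - Y, 1, wts, `*`) / B
        }
        grads <- model_backward(model, fwd$cache, dlogits)
        upd <- rmsprop_update(model$params, grads, state, lr = lr)
        model$params <- upd$p
        state <- upd$s
        ep_loss <- ep_loss + loss; n_batch <- n_batch + 1
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / n_batch,
                        val_f1 = NA_real_, test_f1 = NA_real_)
      if (!is.null(val_samples) && length(val_samples)) {
        vm <- evaluate_samples(model, val_samples)
        row$val_f1 <- vm
      }
      if (!is.null(test_samples) && length(test_samples)) {
        row$test_f1 <- evaluate_samples(model, test_samples)
      }
      metric <- if (!is.null(test_samples)) row$test_f1
        else if (!is.null(val_samples)) row$val_f1 else -row$train_loss
      if (!is.na(metric) && metric > best$metric)
        best <- list(metric = metric, epoch = ep, params = model$params)
      history <- rbind(history, row)
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val F1 %s", ep, row$train_loss,
                        format(row$val_f1, digits = 3)))
    }
  })
  model$params <- best$params
  structure(list(model = model, history = history,
                 selected_epoch = best$epoch, epochs = epochs, seed = seed),
            class = "cacti_fit")
}

# scalar metric for monitoring: transient F1 (activity) or accuracy (type)
evaluate_samples <- function(model, samples) {
  cfg <- model$config
  prob <- predict_samples(model, samples)
  if (is.null(cfg$n_classes)) {
    f1 <- samples_f1(prob, samples)$f1
    if (is.na(f1)) 0 else f1
  } else {
    yi <- vapply(samples, `[[`, numeric(1), "class_label")
    mean(max.col(prob) == yi)
  }
}

#' Per-frame probabilities for a list of patch samples
#' @param model a `cacti_model` or `cacti_fit`.
#' @param samples list of `cacti_patch`.
#' @param batch_size forward batch size.
#' @return matrix `n_samples x seq_len` (activity) or
#'   `n_samples x n_classes` (cell type).
#' @export
predict_samples <- function(model, samples, batch_size = 16) {
  if (inherits(model, "cacti_fit")) model <- model$model
  cfg <- model$config
  n <- length(samples)
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    xs <- stack_samples(samples[sel], cfg)
    fwd <- model_forward(model, xs, train = FALSE)
    out <- rbind(out, fwd$prob)
  }
  out
}

#' Predict per-frame activity over a whole movie
#'
#' The movie is tiled into consecutive non-overlapping `seq_len` blocks; the
#' final block is right-aligned, and frames covered twice get the average of
#' the two block predictions.
#'
#' @param model a `cacti_model` or `cacti_fit` (activity configuration).
#' @param movie `cacti_movie` or frames array.
#' @param cell_map a `cacti_cellmap` (defaults to the movie's).
#' @param cell_ids cells to predict (default all).
#' @param threshold stored activation threshold.
#' @param batch_size forward batch size.
#' @return a `cacti_predictions`.
#' @export
predict_movie <- function(model, movie, cell_map = NULL, cell_ids = NULL,
                          threshold = 0.5, batch_size = 16) {
  if (inherits(model, "cacti_fit")) model <- model$model
  cfg <- model$config
  if (inherits(movie, "cacti_movie") && is.null(cell_map))
    cell_map <- movie$cell_map
  frames <- if (inherits(movie, "cacti_movie")) movie$frames else movie
  nf <- dim(frames)[1]
  if (nf < cfg$seq_len)
    stop_config("predict_movie: movie has %d frames < seq_len %d", nf,
                cfg$seq_len)
  starts <- seq(0L, nf - cfg$seq_len, by = cfg$seq_len)
  if (max(starts) + cfg$seq_len < nf) starts <- c(starts, nf - cfg$seq_len)
  ids <- cell_ids %||% vapply(cell_map$contours, `[[`, integer(1), "cell_id")
  prob <- matrix(0, length(ids), nf)
  cnt <- matrix(0, length(ids), nf)
  for (i in seq_along(ids)) {
    patches <- lapply(starts, function(s0)
      make_streams(frames, cell_map, ids[i], s0, seq_len = cfg$seq_len,
                   window = cfg$window))
    pr <- predict_samples(model, patches, batch_size)
    for (k in seq_along(starts)) {
      fr <- starts[k] + seq_len(cfg$seq_len)
      prob[i, fr] <- prob[i, fr] + pr[k, ]
      cnt[i, fr] <- cnt[i, fr] + 1
    }
  }
  new_predictions(prob / cnt, ids, threshold = threshold)
}

# Two-stream patch for the cell-type model: the cell-masked window and the
# full unmasked context window.
make_celltype_streams <- function(movie, cell_map, cell_id, start_frame,
                                  seq_len = 500, window = 20) {
  full <- make_streams(movie, cell_map, cell_id, start_frame,
                       seq_len = seq_len, window = window)
  raw <- full$stream_cell + full$stream_overlap + full$stream_neuropil
  structure(list(cell_id = full$cell_id, start_frame = full$start_frame,
                 seq_len = full$seq_len, window = full$window,
                 stream_cell = full$stream_cell, stream_overlap = raw,
                 weight = 1), class = "cacti_patch")
}

#' Predict a cell's type from a movie
#'
#' Tiles the movie into `seq_len` windows (right-aligned final window),
#' averages the per-window class probabilities and renormalizes.
#'
#' @param model a cell-type `cacti_model` or `cacti_fit`.
#' @param movie `cacti_movie` or frames array.
#' @param cell_map a `cacti_cellmap`.
#' @param cell_id which cell.
#' @return named numeric vector of class probabilities summing to 1.
#' @export
predict_celltype <- function(model, movie, cell_map = NULL, cell_id) {
  if (inherits(model, "cacti_fit")) model <- model$model
  cfg <- model$config
  if (inherits(movie, "cacti_movie") && is.null(cell_map))
    cell_map <- movie$cell_map
  frames <- if (inherits(movie, "cacti_movie")) movie$frames else movie
  nf <- dim(frames)[1]
  if (nf < cfg$seq_len)
    stop_config("predict_celltype: movie has %d frames < seq_len %d", nf,
                cfg$seq_len)
  starts <- seq(0L, nf - cfg$seq_len, by = cfg$seq_len)
  if (max(starts) + cfg$seq_len < nf) starts <- c(starts, nf - cfg$seq_len)
  patches <- lapply(starts, function(s0)
    make_celltype_streams(frames, cell_map, cell_id, s0,
                          seq_len = cfg$seq_len, window = cfg$window))
  pr <- predict_samples(model, patches)
  avg <- colMeans(pr)
  avg / sum(avg)
}

#' @export
print.cacti_fit <- function(x, ...) {
  cat(sprintf("<cacti_fit> %d epoch(s), selected epoch %d\n",
              x$epochs, x$selected_epoch))
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cacti_fit <- function(object, ...) {
  print(object)
  print(object$model)
  invisible(object)
}

#' @export
predict.cacti_fit <- function(object, movie, ...) {
  predict_movie(object$model, movie, ...)
}

#' Save / load a fitted model with a JSON config sidecar
#' @param fit a `cacti_fit` or `cacti_model`.
#' @param path output path (`.rds`); the sidecar is `<path>.json`.
#' @export
save_model <- function(fit, path) {
  model <- if (inherits(fit, "cacti_fit")) fit$model else fit
  saveRDS(fit, path)
  side <- c(model$config[!vapply(model$config, is.null, logical(1))],
            list(init_seed = model$init_seed,
                 n_params = n_params(model)))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    yaml::write_yaml(side, paste0(path, ".json"))
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
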