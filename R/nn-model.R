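# Model assembly: per-stream CNN features -> temporal soft attention ->
# stacked bidirectional LSTMs; a final LSTM merges the streams. Activity
# model: per-frame sigmoid over seq_len frames. Cell-type model: softmax
# over classes from the last merged state.

#' Configuration of the per-frame activity classifier
#'
#' @param seq_len frames per input sequence (default 100, ~10 s at 10 Hz,
#'   chosen to cover slow interneuron kinetics; configurable).
#' @param window square input window in pixels (default 25).
#' @param n_streams number of masked input streams (3: cell, overlap,
#'   neuropil).
#' @param conv_filters filters of the three 3x3 conv blocks (each followed by
#'   swish and 2x2 max pooling).
#' @param att_units width of the attention scorer.
#' @param recurrent_width LSTM width per direction in the bidirectional
#'   stacks.
#' @param merge_width width of the merging LSTM.
#' @param dropout_rate dropout on the merged recurrent output, in [0, 1).
#' @param lr RMSprop learning rate.
#' @param preset `"paper"` (full-size) or `"desk"` (small, CPU-friendly);
#'   explicit arguments override the preset.
#' @return a `cacti_model_config`.
#' @export
activity_model_config <- function(seq_len = 100, window = 25, n_streams = 3,
                                  conv_filters = NULL, att_units = NULL,
                                  recurrent_width = NULL, merge_width = NULL,
                                  dropout_rate = 0.5, lr = 1e-3,
                                  preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  defaults <- if (preset == "paper")
    list(conv_filters = c(16, 32, 64), recurrent_width = 64,
         merge_width = 64, att_units = 32)
  else list(conv_filters = c(4, 8, 16), recurrent_width = 16,
            merge_width = 32, att_units = 16)
  cfg <- list(seq_len = as.integer(seq_len), window = as.integer(window),
              n_streams = as.integer(n_streams),
              conv_filters = conv_filters %||% defaults$conv_filters,
              att_units = att_units %||% defaults$att_units,
              recurrent_width = recurrent_width %||% defaults$recurrent_width,
              merge_width = merge_width %||% defaults$merge_width,
              dropout_rate = dropout_rate, lr = lr,
              activation = "swish", loss = "binary cross-entropy",
              optimizer = "RMSprop", batch_norm = FALSE,
              n_classes = NULL, preset = preset)
  validate_model_config(cfg)
  structure(cfg, class = "cacti_model_config")
}

#' Configuration of the cell-type classifier
#'
#' Two input streams (cell-masked window and the full unmasked context
#' window), 500-frame sequences of 20x20 windows by default, softmax over
#' three classes (interneuron, pyramidal, noise).
#'
#' @inheritParams activity_model_config
#' @param n_classes number of cell-type classes (default 3).
#' @export
celltype_model_config <- function(seq_len = 500, window = 20, n_streams = 2,
                                  n_classes = 3, conv_filters = NULL,
                                  att_units = NULL, recurrent_width = NULL,
                                  merge_width = NULL, dropout_rate = 0.5,
                                  lr = 1e-3, preset = c("paper", "desk")) {
  cfg <- activity_model_config(seq_len = seq_len, window = window,
                               n_streams = n_streams,
                               conv_filters = conv_filters,
                               att_units = att_units,
                               recurrent_width = recurrent_width,
                               merge_width = merge_width,
                               dropout_rate = dropout_rate, lr = lr,
                               preset = preset)
  cfg$n_classes <- as.integer(n_classes)
  cfg$loss <- "categorical cross-entropy"
  cfg
}

validate_model_config <- function(cfg) {
  if (cfg$seq_len <= 0 || cfg$window <= 0)
    stop_config("model config: seq_len and window must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop_config("model config: dropout_rate must be in [0, 1)")
  w <- cfg$window
  for (f in cfg$conv_filters) w <- w %/% 2L
  if (w < 1) stop_config("model config: window too small for %d conv blocks",
                         length(cfg$conv_filters))
  invisible(cfg)
}

# spatial size and feature dimension after the conv stack
conv_out_dim <- function(cfg) {
  w <- cfg$window
  for (f in cfg$conv_filters) w <- w %/% 2L
  c(side = w, dim = w * w * cfg$conv_filters[length(cfg$conv_filters)])
}

#' Build an activity or cell-type model
#'
#' Initializes all parameters (Glorot uniform, seeded). Each stream gets a
#' structurally identical branch with its own parameters; a final LSTM
#' merges the streams.
#'
#' @param config a `cacti_model_config`.
#' @param seed integer seed for weight initialization.
#' @return a `cacti_model`.
#' @export
build_model <- function(config, seed = 1L) {
  validate_model_config(config)
  D <- conv_out_dim(config)["dim"]
  h <- config$recurrent_width
  with_seed(seed, {
    streams <- lapply(seq_len(config$n_streams), function(s) {
      c_in <- c(1, config$conv_filters[-length(config$conv_filters)])
      list(conv = Map(conv_init, c_in, config$conv_filters),
           att = att_init(D, config$att_units),
           l1 = bilstm_init(D, h),
           l2 = bilstm_init(D + 2 * h, h))
    })
    merge <- lstm_init(2 * h * config$n_streams, config$merge_width)
    out_dim <- config$n_classes %||% 1L
    out <- list(W = glorot(config$merge_width, out_dim),
                b = numeric(out_dim))
    structure(list(config = config,
                   params = list(streams = streams, merge = merge, out = out),
                   init_seed = seed),
              class = "cacti_model")
  })
}

#' @export
print.cacti_model <- function(x, ...) {
  cfg <- x$config
  kind <- if (is.null(cfg$n_classes)) "per-frame activity" else
    sprintf("%d-class cell type", cfg$n_classes)
  cat(sprintf(paste0("<cacti_model> %s classifier\n",
                     "  %d stream(s) of %d x %dx%d frames; conv %s, ",
                     "attention %d, biLSTM %d/dir, merge LSTM %d\n",
                     "  %d parameters\n"),
              kind, cfg$n_streams, cfg$seq_len, cfg$window, cfg$window,
              paste(cfg$conv_filters, collapse = "/"), cfg$att_units,
              cfg$recurrent_width, cfg$merge_width, n_params(x)))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a `cacti_model`.
#' @export
n_params <- function(model) {
  cnt <- function(p) if (is.list(p)) sum(vapply(p, cnt, numeric(1)))
    else length(p)
  cnt(model$params)
}

# ---- forward / backward -----------------------------------------------------

# One branch: frames [B, T, w, w] -> sequence features [B, T, 2h]
branch_forward <- function(x, p, cfg) {
  B <- dim(x)[1]; T <- dim(x)[2]; w <- cfg$window
  z <- x
  dim(z) <- c(B * T, w, w, 1)
  caches <- list()
  for (l in seq_along(p$conv)) {
    cv <- conv_forward(z, p$conv[[l]])
    sg <- sigmoid(cv$out)
    act <- cv$out * sg
    pl <- pool_forward(act)
    caches[[l]] <- list(conv = cv, pre = cv$out, sig = sg, pool = pl)
    z <- pl$out
  }
  feat <- z
  dim(feat) <- c(B * T, prod(dim(z)[-1]))
  at <- att_forward(feat, p$att, B, T)
  g <- at$out
  dim(g) <- c(B, T, ncol(feat))
  b1 <- bilstm_forward(g, p$l1)
  g2 <- array(0, dim = c(B, T, dim(g)[3] + dim(b1$out)[3]))
  g2[, , seq_len(dim(g)[3])] <- g
  g2[, , dim(g)[3] + seq_len(dim(b1$out)[3])] <- b1$out
  b2 <- bilstm_forward(g2, p$l2)
  list(out = b2$out, conv = caches, att = at, b1 = b1, b2 = b2,
       g_dim = dim(g), B = B, T = T)
}

branch_backward <- function(dout, cache, p, cfg) {
  B <- cache$B; T <- cache$T
  d2 <- bilstm_backward(dout, cache$b2, p$l2)
  Dg <- cache$g_dim[3]
  dg <- d2$dx[, , seq_len(Dg), drop = FALSE]
  db1out <- d2$dx[, , Dg + seq_len(dim(cache$b1$out)[3]), drop = FALSE]
  d1 <- bilstm_backward(db1out, cache$b1, p$l1)
  dg <- dg + d1$dx
  dgm <- dg
  dim(dgm) <- c(B * T, Dg)
  da <- att_backward(dgm, cache$att, p$att)
  dz <- da$dfeat
  last <- cache$conv[[length(cache$conv)]]
  dim(dz) <- dim(last$pool$out)
  conv_grads <- vector("list", length(p$conv))
  for (l in rev(seq_along(p$conv))) {
    cc <- cache$conv[[l]]
    dact <- pool_backward(dz, cc$pool)
    dpre <- dact * (cc$sig * (1 + cc$pre * (1 - cc$sig)))
    cb <- conv_backward(dpre, cc$conv, p$conv[[l]])
    conv_grads[[l]] <- cb$grad
    dz <- cb$dx
  }
  list(grad = list(conv = conv_grads, att = da$grad,
                   l1 = d1$grad, l2 = d2$grad))
}

# Full forward. x: list of stream arrays [B, T, w, w]. Training mode applies
# dropout (seeded by the caller's RNG state).
model_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- model$params
  stopifnot(length(x) == cfg$n_streams)
  B <- dim(x[[1]])[1]; T <- dim(x[[1]])[2]
  branches <- lapply(seq_len(cfg$n_streams), function(s)
    branch_forward(x[[s]], p$streams[[s]], cfg))
  hcat <- array(0, dim = c(B, T, 2 * cfg$recurrent_width * cfg$n_streams))
  for (s in seq_len(cfg$n_streams)) {
    off <- (s - 1) * 2 * cfg$recurrent_width
    hcat[, , off + seq_len(2 * cfg$recurrent_width)] <- branches[[s]]$out
  }
  mg <- lstm_forward(hcat, p$merge)
  hm <- mg$out
  drop_mask <- NULL
  if (train && cfg$dropout_rate > 0) {
    drop_mask <- array(stats::rbinom(length(hm), 1, 1 - cfg$dropout_rate) /
                         (1 - cfg$dropout_rate), dim = dim(hm))
    hm <- hm * drop_mask
  }
  if (is.null(cfg$n_classes)) {
    hmat <- hm
    dim(hmat) <- c(B * T, cfg$merge_width)
    logits <- sweep(hmat %*% p$out$W, 2, p$out$b, `+`)
    prob <- matrix(sigmoid(logits), B, T)
    list(prob = prob, cache = list(branches = branches, merge = mg,
                                   hm = hm, drop_mask = drop_mask,
                                   hmat = hmat, B = B, T = T))
  } else {
    hlast <- matrix(hm[, T, ], B, cfg$merge_width)
    logits <- sweep(hlast %*% p$out$W, 2, p$out$b, `+`)
    el <- exp(logits - apply(logits, 1, max))
    prob <- el / rowSums(el)
    list(prob = prob, cache = list(branches = branches, merge = mg,
                                   hm = hm, drop_mask = drop_mask,
                                   hlast = hlast, B = B, T = T))
  }
}

# Backward from d(logits). dlogits: activity (B*T) x 1; celltype B x classes.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  B <- cache$B; T <- cache$T
  if (is.null(cfg$n_classes)) {
    dW <- crossprod(cache$hmat, dlogits)
    db <- colSums(dlogits)
    dhm <- tcrossprod(dlogits, p$out$W)
    dim(dhm) <- c(B, T, cfg$merge_width)
  } else {
    dW <- crossprod(cache$hlast, dlogits)
    db <- colSums(dlogits)
    dhm <- array(0, dim = c(B, T, cfg$merge_width))
    dhm[, T, ] <- tcrossprod(dlogits, p$out$W)
  }
  if (!is.null(cache$drop_mask)) dhm <- dhm * cache$drop_mask
  dm <- lstm_backward(dhm, cache$merge, p$merge)
  stream_grads <- vector("list", cfg$n_streams)
  for (s in seq_len(cfg$n_streams)) {
    off <- (s - 1) * 2 * cfg$recurrent_width
    dbr <- dm$dx[, , off + seq_len(2 * cfg$recurrent_width), drop = FALSE]
    stream_grads[[s]] <- branch_backward(dbr, cache$branches[[s]],
                                         p$streams[[s]], cfg)$grad
  }
  list(streams = stream_grads, merge = dm$grad,
       out = list(W = dW, b = db))
}
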