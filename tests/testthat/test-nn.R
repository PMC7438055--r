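# The classifier network: layer correctness (against naive references and
# finite differences), determinism, output contracts, and temporal locality.

test_that("the convolution layer matches a naive nested-loop reference", {
  set.seed(3)
  n <- 3; h <- 6; w <- 5; cin <- 2; cout <- 3
  x <- array(rnorm(n * h * w * cin), c(n, h, w, cin))
  p <- cacti:::conv_init(cin, cout)
  out <- cacti:::conv_forward(x, p)$out
  ref <- array(0, c(n, h, w, cout))
  for (ni in 1:n) for (i in 1:h) for (j in 1:w) for (f in 1:cout) {
    acc <- p$b[f]; k <- 1
    for (dy in -1:1) for (dx in -1:1) {
      ii <- i + dy; jj <- j + dx
      for (ci in 1:cin) {
        v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
          x[ni, ii, jj, ci] else 0
        acc <- acc + v * p$W[(k - 1) * cin + ci, f]
      }
      k <- k + 1
    }
    ref[ni, i, j, f] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("max pooling selects window maxima and routes gradient only to them", {
  set.seed(4)
  x <- array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2))
  pl <- cacti:::pool_forward(x)
  for (ni in 1:2) for (i in 1:3) for (j in 1:3) for (ci in 1:2)
    expect_equal(pl$out[ni, i, j, ci],
                 max(x[ni, 2 * i - 1:0, 2 * j - 1:0, ci]))
  dout <- array(1, dim = dim(pl$out))
  dx <- cacti:::pool_backward(dout, pl)
  # each 2x2 window received exactly one unit of gradient, at its argmax
  for (ni in 1:2) for (i in 1:3) for (j in 1:3) for (ci in 1:2) {
    blk <- dx[ni, 2 * i - 1:0, 2 * j - 1:0, ci]
    expect_equal(sum(blk), 1)
    expect_equal(x[ni, 2 * i - 1:0, 2 * j - 1:0, ci][blk == 1],
                 pl$out[ni, i, j, ci])
  }
})

test_that("uninformative attention acts as the identity on the feature sequence", {
  set.seed(5)
  D <- 6; B <- 2; T <- 4
  p <- cacti:::att_init(D, 3)
  p$va[] <- 0            # constant scores -> uniform weights
  feat <- matrix(rnorm(B * T * D), B * T, D)
  out <- cacti:::att_forward(feat, p, B, T)$out
  # weights 1/T, rescaled by T: features pass through unchanged
  expect_equal(out, feat, tolerance = 1e-12)
})

test_that("every parameter's analytic gradient matches finite differences", {
  set.seed(42)
  cfg <- tiny_activity_config()
  model <- build_model(cfg, seed = 99)
  B <- 2L; T <- cfg$seq_len; w <- cfg$window
  x <- lapply(seq_len(cfg$n_streams), function(s)
    array(runif(B * T * w * w), c(B, T, w, w)))
  y <- matrix(rbinom(B * T, 1, 0.5), B, T)
  wts <- c(1, 2)
  loss_fn <- function(params) {
    m <- model; m$params <- params
    p <- cacti:::model_forward(m, x, train = FALSE)$prob
    sum(sweep(-(y * log(p) + (1 - y) * log(1 - p)), 1, wts, `*`)) / (B * T)
  }
  fw <- cacti:::model_forward(model, x, train = FALSE)
  dl <- sweep(fw$prob - y, 1, wts, `*`) / (B * T)
  gr <- cacti:::model_backward(model, fw$cache, matrix(as.vector(dl), ncol = 1))
  set.seed(7)
  for (lf in flatten_params(model$params)) {
    i <- sample.int(lf$len, 1)
    base <- get_leaf(model$params, lf$path)[i]
    num <- (loss_fn(set_leaf(model$params, lf$path, i, base + 1e-5)) -
              loss_fn(set_leaf(model$params, lf$path, i, base - 1e-5))) / 2e-5
    ana <- get_leaf(gr, lf$path)[i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
  }
})

test_that("the cell-type head produces a probability simplex and exact softmax gradients", {
  set.seed(21)
  cfg <- celltype_model_config(seq_len = 6, window = 9, n_streams = 2,
                               n_classes = 3, conv_filters = c(2L, 3L, 4L),
                               att_units = 3L, recurrent_width = 2L,
                               merge_width = 4L, preset = "desk")
  model <- build_model(cfg, seed = 22)
  B <- 2L
  x <- lapply(1:2, function(s) array(runif(B * 6 * 81), c(B, 6, 9, 9)))
  prob <- cacti:::model_forward(model, x, train = FALSE)$prob
  expect_equal(dim(prob), c(2L, 3L))
  expect_equal(rowSums(prob), c(1, 1), tolerance = 1e-9)
  yi <- c(1L, 3L)
  Y <- matrix(0, B, 3); Y[cbind(1:B, yi)] <- 1
  loss_fn <- function(params) {
    m <- model; m$params <- params
    p <- cacti:::model_forward(m, x, train = FALSE)$prob
    -mean(rowSums(Y * log(p)))
  }
  fw <- cacti:::model_forward(model, x, train = FALSE)
  gr <- cacti:::model_backward(model, fw$cache, (fw$prob - Y) / B)
  set.seed(8)
  leaves <- flatten_params(model$params)
  for (lf in leaves[sample.int(length(leaves), 10)]) {
    i <- sample.int(lf$len, 1)
    base <- get_leaf(model$params, lf$path)[i]
    num <- (loss_fn(set_leaf(model$params, lf$path, i, base + 1e-5)) -
              loss_fn(set_leaf(model$params, lf$path, i, base - 1e-5))) / 2e-5
    ana <- get_leaf(gr, lf$path)[i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
  }
})

test_that("model construction and forward passes are deterministic and batch-separating", {
  cfg <- tiny_activity_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  set.seed(12)
  B <- 2L; T <- cfg$seq_len; w <- cfg$window
  x <- lapply(1:cfg$n_streams, function(s)
    array(runif(B * T * w * w), c(B, T, w, w)))
  p0 <- cacti:::model_forward(m1, x, train = FALSE)$prob
  expect_true(all(p0 > 0 & p0 < 1))
  # perturbing sample 1 leaves sample 2's predictions untouched
  x2 <- x
  x2[[1]][1, , , ] <- x2[[1]][1, , , ] + 0.5
  p1 <- cacti:::model_forward(m1, x2, train = FALSE)$prob
  expect_equal(p1[2, ], p0[2, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p1[1, ], p0[1, ])))
})

test_that("predictions respond to when a frame brightens, not only whether", {
  cfg <- tiny_activity_config(seq_len = 8)
  model <- build_model(cfg, seed = 31)
  set.seed(32)
  base <- array(runif(1 * 8 * 81, 0, 0.1), c(1, 8, 9, 9))
  mk <- function(t_on) {
    a <- base; a[1, t_on, , ] <- a[1, t_on, , ] + 1
    lapply(1:cfg$n_streams, function(s) a)
  }
  p3 <- cacti:::model_forward(model, mk(3), train = FALSE)$prob
  p6 <- cacti:::model_forward(model, mk(6), train = FALSE)$prob
  expect_false(isTRUE(all.equal(as.vector(p3), as.vector(p6))))
})

test_that("parameter counts follow the architecture arithmetic", {
  cfg <- tiny_activity_config()
  model <- build_model(cfg, seed = 1)
  f <- cfg$conv_filters; h <- cfg$recurrent_width
  D <- 9 * f[3]           # window 9 -> 4 -> 2 -> 1 spatial, so D = filters3
  side <- cfg$window
  for (k in 1:3) side <- side %/% 2
  D <- side * side * f[3]
  conv_n <- (9 * 1 * f[1] + f[1]) + (9 * f[1] * f[2] + f[2]) +
    (9 * f[2] * f[3] + f[3])
  att_n <- D * cfg$att_units + 2 * cfg$att_units
  lstm_n <- function(din, hh) 4 * (din * hh + hh * hh + hh)
  branch <- conv_n + att_n + 2 * lstm_n(D, h) + 2 * lstm_n(D + 2 * h, h)
  total <- cfg$n_streams * branch +
    lstm_n(2 * h * cfg$n_streams, cfg$merge_width) +
    cfg$merge_width * 1 + 1
  expect_equal(n_params(model), total)
})

test_that("rmsprop updates every leaf of a nested parameter structure", {
  p <- list(a = matrix(1, 2, 2), b = list(c = rep(0.5, 3)))
  g <- list(a = matrix(1, 2, 2), b = list(c = rep(2, 3)))
  upd <- cacti:::rmsprop_update(p, g, NULL, lr = 0.01)
  expect_true(all(upd$p$a < p$a))
  expect_true(all(upd$p$b$c < p$b$c))
  # second step reuses accumulated state
  upd2 <- cacti:::rmsprop_update(upd$p, g, upd$s, lr = 0.01)
  expect_true(all(upd2$p$a < upd$p$a))
})

test_that("training with a fixed seed is exactly reproducible", {
  cfg <- tiny_activity_config()
  set.seed(51)
  mk_sample <- function() {
    T <- cfg$seq_len; w <- cfg$window
    structure(list(stream_cell = array(runif(T * w * w), c(T, w, w)),
                   stream_overlap = array(runif(T * w * w), c(T, w, w)),
                   stream_neuropil = array(0, c(T, w, w)),
                   label = rbinom(T, 1, 0.3), weight = 1,
                   cell_id = 1L, start_frame = 0L, seq_len = T, window = w),
              class = "cacti_patch")
  }
  samples <- replicate(6, mk_sample(), simplify = FALSE)
  m <- build_model(cfg, seed = 3)
  f1 <- cacti_train(m, samples, epochs = 2, batch_size = 3, seed = 77)
  f2 <- cacti_train(m, samples, epochs = 2, batch_size = 3, seed = 77)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$history$train_loss, f2$history$train_loss)
})

test_that("a saved model reloads with identical predictions", {
  cfg <- tiny_activity_config()
  model <- build_model(cfg, seed = 61)
  fit <- structure(list(model = model, history = data.frame(),
                        selected_epoch = 1L, epochs = 1L, seed = 61L),
                   class = "cacti_fit")
  path <- file.path(tempdir(), "model_test.rds")
  save_model(fit, path)
  back <- load_model(path)
  set.seed(62)
  B <- 1L; T <- cfg$seq_len; w <- cfg$window
  x <- lapply(1:cfg$n_streams, function(s)
    array(runif(B * T * w * w), c(B, T, w, w)))
  expect_identical(cacti:::model_forward(back$model, x, FALSE)$prob,
                   cacti:::model_forward(model, x, FALSE)$prob)
  unlink(c(path, paste0(path, ".json")))
})

test_that("movie inference tiles with a right-aligned last block and averages the overlap", {
  cfg <- tiny_activity_config(seq_len = 5)
  model <- build_model(cfg, seed = 71)
  mask <- as.matrix(expand.grid(x = 5:12, y = 5:12))
  ct <- structure(list(cell_id = 1L, mask = mask,
                       nucleus_mask = mask[1:2, , drop = FALSE],
                       soma_mask = mask[-(1:2), , drop = FALSE],
                       vertices = NULL, centroid = colMeans(mask)),
                  class = "cacti_contour")
  cmap <- structure(list(contours = list(ct), field_shape = c(20L, 20L)),
                    class = "cacti_cellmap")
  set.seed(72)
  frames <- array(runif(13 * 400), c(13, 20, 20))
  preds <- predict_movie(model, frames, cmap)
  expect_identical(dim(preds$prob), c(1L, 13L))
  # blocks [0,5), [5,10), [8,13): frames 8-9 (0-based) belong to two blocks
  pr <- vapply(c(0L, 5L, 8L), function(s0) {
    p <- make_streams(frames, cmap, 1L, s0, seq_len = 5, window = cfg$window)
    as.vector(predict_samples(model, list(p)))
  }, numeric(5))
  expect_equal(preds$prob[1, 1:5], pr[, 1])
  expect_equal(preds$prob[1, 6:8], pr[1:3, 2])
  expect_equal(preds$prob[1, 9:10], (pr[4:5, 2] + pr[1:2, 3]) / 2)
  expect_equal(preds$prob[1, 11:13], pr[3:5, 3])
})

test_that("the cell-type model separates kinetic regimes above chance on held-out cells", {
  cfg <- celltype_model_config(seq_len = 12, window = 9, n_streams = 2,
                               n_classes = 3, conv_filters = c(2L, 3L, 4L),
                               att_units = 3L, recurrent_width = 3L,
                               merge_width = 6L, lr = 5e-3, preset = "desk")
  set.seed(81)
  mk_sample <- function(class) {
    T <- cfg$seq_len; w <- cfg$window
    tr <- switch(class,
                 numeric(T) + c(rep(0, 3), 1, rep(0, T - 4)),  # brief blip
                 c(rep(0, 3), rep(1, T - 3)),                  # plateau
                 numeric(T))                                   # silent
    base <- array(runif(T * w * w, 0, 0.1), c(T, w, w))
    cell <- base
    cell[, 3:7, 3:7] <- cell[, 3:7, 3:7] + tr * 0.8
    structure(list(stream_cell = cell, stream_overlap = base,
                   label = NULL, class_label = class, weight = 1,
                   cell_id = 1L, start_frame = 0L, seq_len = T, window = w),
              class = "cacti_patch")
  }
  train <- lapply(rep(1:3, each = 15), mk_sample)
  test <- lapply(rep(1:3, each = 5), mk_sample)
  model <- build_model(cfg, seed = 82)
  fit <- cacti_train(model, train, epochs = 8, batch_size = 5, seed = 83)
  prob <- predict_samples(fit, test)
  acc <- mean(max.col(prob) == vapply(test, `[[`, numeric(1), "class_label"))
  expect_gt(acc, 1 / 3)
})
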