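# Patch pipeline: temporal segmentation, masked streams, augmentation,
# segment classes, stratification and the cell-wise split.

test_that("stride-10 segmentation tiles the movie with full coverage", {
  starts <- temporal_segments(1000, seq_len = 100, stride = 10)
  expect_equal(starts[1], 0)
  expect_equal(max(starts) + 100, 1000)
  expect_equal(diff(starts), rep(10, length(starts) - 1))
  # short movies still yield the single full-length segment
  expect_equal(temporal_segments(100, 100, 10), 0)
  expect_error(temporal_segments(99, 100, 10), "")
})

test_that("the three masked streams partition the normalized raw patch exactly", {
  movie <- fixture_movie()
  labels <- fixture_labels()
  for (cell in c(1L, 7L)) {
    s <- make_streams(movie, movie$cell_map, cell, 40, seq_len = 100,
                      window = 25, labels = labels)
    total <- s$stream_cell + s$stream_overlap + s$stream_neuropil
    raw <- make_streams(movie, movie$cell_map, cell, 40, seq_len = 100,
                        window = 25)
    full <- raw$stream_cell + raw$stream_overlap + raw$stream_neuropil
    expect_equal(total, full, tolerance = 1e-12)
    # streams have disjoint support
    expect_true(all((s$stream_cell != 0) + (s$stream_overlap != 0) +
                      (s$stream_neuropil != 0) <= 1))
    expect_true(all(total >= 0 & total <= 1))
    expect_length(s$label, 100)
  }
})

test_that("patch labels equal the ground-truth raster restricted to the segment", {
  movie <- fixture_movie()
  labels <- fixture_labels()
  raster <- labels_to_raster(labels)
  s <- make_streams(movie, movie$cell_map, 3L, 50, seq_len = 100,
                    window = 25, labels = labels)
  i <- match(3L, labels$cell_ids)
  expect_equal(as.numeric(s$label), as.numeric(raster[i, 50 + 1:100]))
})

test_that("spatial augmentations are lattice-exact involutions and rotations", {
  movie <- fixture_movie()
  s <- make_streams(movie, movie$cell_map, 2L, 0, seq_len = 100, window = 25)
  fh <- augment_spatial(augment_spatial(s, "flip_h"), "flip_h")
  expect_equal(fh$stream_cell, s$stream_cell, tolerance = 1e-12)
  r4 <- s
  for (i in 1:4) r4 <- augment_spatial(r4, "rot90", k = 1)
  expect_equal(r4$stream_cell, s$stream_cell, tolerance = 1e-12)
  tr <- augment_spatial(s, "translate", dx = 2, dy = -1)
  # translation moves pixel content exactly (interior pixels)
  expect_equal(tr$stream_cell[5, 10, 10], s$stream_cell[5, 10 + 1, 10 - 2],
               tolerance = 1e-12)
})

test_that("translations that would push the cell out of frame are refused", {
  movie <- fixture_movie()
  s <- make_streams(movie, movie$cell_map, 2L, 0, seq_len = 100, window = 25)
  expect_error(augment_spatial(s, "translate", dx = 25, dy = 0), "")
})

test_that("segment classes distinguish real, fake-only and empty content", {
  labels <- new_labels(list(cbind(10L, 14L)), 1L, 300L)
  put <- new_labels(list(cbind(c(10L, 150L), c(14L, 155L))), 1L, 300L)
  expect_identical(classify_segment(labels, put, 1L, 0, 100), "REAL")
  expect_identical(classify_segment(labels, put, 1L, 120, 100), "FAKE_ONLY")
  expect_identical(classify_segment(labels, put, 1L, 200, 100), "EMPTY")
})

test_that("stratification hits the 60/30/10 target and weights fake segments five-fold", {
  set.seed(5)
  classes <- sample(c(rep("REAL", 500), rep("FAKE_ONLY", 300),
                      rep("EMPTY", 200)))
  out <- stratify(classes, n_out = 200, seed = 9)
  tab <- table(out$class) / nrow(out)
  expect_equal(unname(tab["REAL"]), 0.6, tolerance = 0.02)
  expect_equal(unname(tab["FAKE_ONLY"]), 0.3, tolerance = 0.02)
  expect_equal(unname(tab["EMPTY"]), 0.1, tolerance = 0.02)
  expect_true(all(out$weight[out$class == "FAKE_ONLY"] == 5))
  expect_true(all(out$weight[out$class != "FAKE_ONLY"] == 1))
  expect_true(all(out$index %in% seq_along(classes)))
  expect_identical(classes[out$index], as.character(out$class))
})

test_that("scarce classes are oversampled with augmentation flags", {
  classes <- c(rep("REAL", 100), rep("FAKE_ONLY", 4), rep("EMPTY", 20))
  out <- stratify(classes, n_out = 100, seed = 3)
  fake <- out[out$class == "FAKE_ONLY", ]
  expect_gt(nrow(fake), 4)             # replicated beyond the pool
  expect_true(any(fake$augment))       # replicates marked for augmentation
})

test_that("the train/validation split never places one cell on both sides", {
  ids <- rep(1:16, times = 12)
  sp <- split_train_validation(ids, ratio = 0.8, seed = 4)
  expect_length(intersect(sp$train_cells, sp$val_cells), 0)
  expect_setequal(c(sp$train_cells, sp$val_cells), 1:16)
  expect_gte(length(sp$train_cells), 12)
})
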