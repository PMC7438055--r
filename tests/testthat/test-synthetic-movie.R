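# Generative model of the synthetic movies: cell geometry, transient
# kinetics, pixel model, and reproducibility.

test_that("contours have bounded radii, a nucleus inside the soma, and an exact soma/nucleus partition", {
  lib <- generate_contour_library(12, geometry_config(), seed = 21)
  for (ct in lib) {
    # radius 4-8 px with <= 20% jitter and eccentricity <= 2 bounds the
    # extent: no vertex can be farther than 8 * 1.2 from the centroid
    ext <- max(abs(ct$mask[, 1] - mean(ct$mask[, 1])),
               abs(ct$mask[, 2] - mean(ct$mask[, 2])))
    expect_lte(ext, 8 * 1.2 + 1)
    expect_gte(nrow(ct$mask), 5)
    key <- function(px) px[, 1] * 1000 + px[, 2]
    expect_true(all(key(ct$nucleus_mask) %in% key(ct$mask)))
    expect_true(all(key(ct$soma_mask) %in% key(ct$mask)))
    # soma and nucleus partition the mask exactly
    expect_length(intersect(key(ct$soma_mask), key(ct$nucleus_mask)), 0)
    expect_setequal(c(key(ct$soma_mask), key(ct$nucleus_mask)), key(ct$mask))
    # concentric nucleus at half scale covers less than half the area
    expect_lt(nrow(ct$nucleus_mask), nrow(ct$mask) * 0.6)
  }
})

test_that("contour generation is deterministic under a fixed seed", {
  a <- generate_contour_library(6, geometry_config(), seed = 5)
  b <- generate_contour_library(6, geometry_config(), seed = 5)
  expect_identical(a, b)
  d <- generate_contour_library(6, geometry_config(), seed = 6)
  expect_false(identical(a, d))
})

test_that("cell maps give every cell between 1 and 4 overlapping neighbours", {
  movie <- fixture_movie()
  cmap <- movie$cell_map
  expect_length(cmap$contours, 16)
  deg <- overlap_degrees(cmap)
  expect_true(all(deg >= 1 & deg <= 4))
  # all pixels inside the field of view
  for (ct in cmap$contours) {
    expect_true(all(ct$mask[, 1] >= 0 & ct$mask[, 1] < cmap$field_shape[2]))
    expect_true(all(ct$mask[, 2] >= 0 & ct$mask[, 2] < cmap$field_shape[1]))
  }
})

test_that("transient schedules respect the per-1000-frame count law and event invariants", {
  for (seed in 1:10) {
    s <- sample_activity(1000, seed = seed)
    expect_gte(nrow(s$events), 2)
    expect_lte(nrow(s$events), 16)
    ev <- s$events
    expect_true(all(ev$rise_len >= 1 & ev$rise_len <= 8))
    expect_true(all(ev$decay_tau >= 10 & ev$decay_tau <= 12))
    expect_true(all(ev$amplitude > 0))
    expect_identical(ev$peak, ev$onset + ev$rise_len)
    expect_true(all(ev$peak < s$n_frames))
    expect_false(any(duplicated(ev$onset)))
  }
  # counts scale proportionally with movie length
  s3 <- sample_activity(3000, seed = 1)
  expect_gte(nrow(s3$events), 6)
  expect_lte(nrow(s3$events), 48)
})

test_that("rendered traces rise linearly to the amplitude and decay with the stated time constant", {
  sched <- sample_activity(200, seed = 3)
  sched$events <- data.frame(onset = 50L, rise_len = 4L, peak = 54L,
                             decay_tau = 10, amplitude = 2)
  tr <- render_trace(sched)
  expect_length(tr, 200)
  expect_equal(tr[50 + 1], 0)                      # onset frame (0-based 50)
  expect_equal(tr[52 + 1], 1, tolerance = 1e-12)   # linear midpoint
  expect_equal(tr[54 + 1], 2, tolerance = 1e-12)   # peak = amplitude
  # one decay time constant after the peak the trace has fallen to a/e
  expect_equal(tr[64 + 1], 2 * exp(-1), tolerance = 1e-9)
  expect_true(all(tr[1:50] == 0))
})

test_that("overlapping transients of one cell sum", {
  sched <- sample_activity(200, seed = 3)
  sched$events <- data.frame(onset = c(50L, 52L), rise_len = c(4L, 4L),
                             peak = c(54L, 56L), decay_tau = c(10, 10),
                             amplitude = c(2, 1))
  tr2 <- render_trace(sched)
  sched$events <- sched$events[1, ]
  tr_a <- render_trace(sched)
  # second event contributes 0.5 at frame 54 (its linear midpoint)
  expect_equal(tr2[54 + 1], tr_a[54 + 1] + 0.5, tolerance = 1e-9)
})

test_that("noiseless pixels equal baseline plus gain-weighted trace, nucleus dimmer than soma", {
  lib <- generate_contour_library(32, geometry_config(), seed = 7)
  cmap <- build_cell_map(lib, n_cells = 4, field_shape = c(60, 60), seed = 8)
  traces <- matrix(0, 4, 120)
  traces[1, 30] <- 1.5
  mv <- render_movie(cmap, traces, noise = noise_params(sigma2 = 0),
                     texture_sd = 0, seed = 9)
  h <- 60
  ct <- cmap$contours[[1]]
  soma_px <- ct$soma_mask[1, ]; nuc_px <- ct$nucleus_mask[1, ]
  # exclusive pixels only (no other cell's gain on top)
  expect_equal(mv$frames[30, soma_px[2] + 1, soma_px[1] + 1] -
                 mv$frames[29, soma_px[2] + 1, soma_px[1] + 1],
               1.0 * 1.5, tolerance = 1e-9)
  expect_equal(mv$frames[30, nuc_px[2] + 1, nuc_px[1] + 1] -
                 mv$frames[29, nuc_px[2] + 1, nuc_px[1] + 1],
               0.6 * 1.5, tolerance = 1e-9)
  # off-cell pixel untouched
  expect_equal(mv$frames[30, 1, 1], mv$frames[29, 1, 1])
})

test_that("full simulation is reproducible from the master seed", {
  a <- simulate_movie(n_frames = 100, n_cells = 4, field_shape = c(50, 50),
                      library_size = 16, seed = 31)
  b <- simulate_movie(n_frames = 100, n_cells = 4, field_shape = c(50, 50),
                      library_size = 16, seed = 31)
  expect_identical(a$frames, b$frames)
  expect_identical(movie_labels(a)$intervals, movie_labels(b)$intervals)
})

test_that("ground-truth labels mark exactly the merged rise intervals of the schedules", {
  movie <- fixture_movie()
  labels <- movie_labels(movie)
  expect_s3_class(labels, "cacti_labels")
  for (i in seq_along(labels$cell_ids)) {
    sch <- movie$schedules[[i]]
    iv <- labels$intervals[[i]]
    # every event's onset..peak is covered by some labeled interval
    for (k in seq_len(nrow(sch$events)))
      expect_true(any(iv[, 1] <= sch$events$onset[k] &
                        iv[, 2] >= sch$events$peak[k]))
    # intervals are disjoint and sorted
    if (nrow(iv) > 1) expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
  }
})
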