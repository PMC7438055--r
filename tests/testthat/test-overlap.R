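# Overlap analysis: eligible pairs, spatial profiles, false-transient
# verdicts on constructed scenes, and the classifier audit.

# A deterministic two-cell scene: cells share a block of pixels; only cell A
# fires, so A's bleed-through creates a fake rise in B's trace.
overlap_scene <- function() {
  mk_mask <- function(x0, x1, y0, y1)
    as.matrix(expand.grid(x = x0:x1, y = y0:y1))
  mask_a <- mk_mask(5, 14, 8, 17)        # 10x10 block
  mask_b <- mk_mask(12, 21, 8, 17)       # overlaps columns 12-14 (30 px)
  ct <- function(id, m) {
    nuc <- m[m[, 1] %% 2 == 0 & m[, 2] %% 2 == 0, , drop = FALSE][1:4, ]
    structure(list(cell_id = id, mask = m, nucleus_mask = nuc,
                   soma_mask = m[!(m[, 1] * 1e4 + m[, 2]) %in%
                                   (nuc[, 1] * 1e4 + nuc[, 2]), ,
                                 drop = FALSE],
                   vertices = NULL, centroid = colMeans(m)),
              class = "cacti_contour")
  }
  cmap <- structure(list(contours = list(ct(1L, mask_a), ct(2L, mask_b)),
                         field_shape = c(30L, 30L)),
                    class = "cacti_cellmap")
  n_frames <- 130
  frames <- array(0.02, c(n_frames, 30, 30))
  lin <- function(m) m[, 2] + 1L + m[, 1] * 30L
  mk_trace <- function(onsets, amp) {
    tr <- numeric(n_frames)
    for (on in onsets) {                   # 0-based onsets, rise 3, decay
      tr[(on:(on + 3)) + 1] <- seq(0, amp, length.out = 4)
      dec <- (on + 4):(min(n_frames - 1, on + 20))
      tr[dec + 1] <- tr[dec + 1] + amp * exp(-(seq_along(dec)) / 8)
    }
    tr
  }
  tr_a <- mk_trace(c(20, 60, 90), 1)       # A's real activity (bleeds into B)
  tr_b <- mk_trace(c(40, 75, 104), 4)      # B's own, stronger activity
  for (t in seq_len(n_frames)) {
    fb <- matrix(0.02, 30, 30)
    fb[lin(mask_a)] <- fb[lin(mask_a)] + tr_a[t]
    fb[lin(mask_b)] <- fb[lin(mask_b)] + tr_b[t]
    frames[t, , ] <- fb
  }
  # A's putative rises are its real ones; B's trace additionally shows
  # bleed-through rises co-timed with A's activity
  putative <- new_labels(
    list(cbind(c(20L, 60L, 90L), c(23L, 63L, 93L)),
         cbind(c(20L, 40L, 60L, 75L, 90L, 104L),
               c(23L, 43L, 63L, 78L, 93L, 107L))),
    cell_ids = c(1L, 2L), n_frames = n_frames)
  list(cmap = cmap, frames = frames, putative = putative)
}

test_that("overlap pairs require at least 15 percent shared area of the larger footprint", {
  sc <- overlap_scene()
  pairs <- find_overlap_pairs(sc$cmap)
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$shared_area_fraction, 30 / 100)
  # raising the bar above the actual fraction removes the pair
  expect_identical(nrow(find_overlap_pairs(sc$cmap, min_fraction = 0.5)), 0L)
})

test_that("overlap fractions agree with a direct pixel-count oracle on simulated maps", {
  cmap <- fixture_movie()$cell_map
  pairs <- find_overlap_pairs(cmap, min_fraction = 1e-9)
  key <- function(ct) ct$mask[, 1] * 10000 + ct$mask[, 2]
  ids <- vapply(cmap$contours, `[[`, integer(1), "cell_id")
  for (k in seq_len(nrow(pairs))) {
    a <- cmap$contours[[match(pairs$cell_a[k], ids)]]
    b <- cmap$contours[[match(pairs$cell_b[k], ids)]]
    inter <- length(intersect(key(a), key(b)))
    expect_equal(pairs$shared_area_fraction[k],
                 inter / max(nrow(a$mask), nrow(b$mask)))
  }
})

test_that("a bleed-through rise is attributed to the truly active neighbour", {
  sc <- overlap_scene()
  verdicts <- detect_false_transients(sc$frames, sc$cmap, sc$putative)
  fake_b <- verdicts[verdicts$cell_id == 2 &
                       verdicts$verdict == "FALSE_TRANSIENT", ]
  expect_gte(nrow(fake_b), 1)
  expect_true(all(fake_b$source_cell == 1))
  # cell A's own rises are never flagged
  expect_identical(nrow(verdicts[verdicts$cell_id == 1 &
                                   verdicts$verdict == "FALSE_TRANSIENT", ]),
                   0L)
})

test_that("transient profiles need a rise of at least one frame", {
  sc <- overlap_scene()
  expect_error(transient_profile(sc$frames, 10, 10), "")
  prof <- transient_profile(sc$frames, 20, 23)
  expect_identical(dim(prof), c(30L, 30L))
  # the profile lights up inside the active cell and not elsewhere
  expect_gt(prof[10, 8], prof[2, 2] + 0.2)
})

test_that("source profiles average a cell's transients into its spatial fingerprint", {
  sc <- overlap_scene()
  src <- source_profile(sc$frames, sc$putative, 1L)
  inside <- src[9:18, 6:15]
  outside <- src[25:30, 25:30]
  expect_gt(mean(inside), mean(outside) + 0.5)
})

test_that("the audit counts a false transient as rejected iff no rise frame is predicted active", {
  fdf <- data.frame(cell_id = c(1L, 1L, 2L), onset = c(5L, 20L, 8L),
                    peak = c(8L, 24L, 10L))
  prob <- matrix(0, 2, 40)
  prob[1, 22] <- 0.9    # frame 21 (0-based) inside 20..24 -> NOT rejected
  preds <- new_predictions(prob, cell_ids = c(1L, 2L))
  audit <- audit_classifier(fdf, preds, threshold = 0.5)
  expect_identical(audit$n_total, 3L)
  expect_identical(audit$n_rejected, 2L)
  expect_equal(audit$fraction_rejected, 2 / 3)
  # nothing to audit yields NA, never a spurious 0 or 1
  empty <- audit_classifier(fdf[0, ], preds)
  expect_true(is.na(empty$fraction_rejected))
})
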