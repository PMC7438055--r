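# Model-ready samples: masked three-stream patches, temporal segmentation,
# spatial augmentation, segment classification, stratification, splitting.

# Centroid of a mask rounded half-up, as (cx, cy).
mask_centroid <- function(mask) floor(colMeans(mask) + 0.5)

#' Build the masked three-stream patch for one cell and segment
#'
#' A `window x window` crop centered on the cell's mask centroid is taken for
#' `seq_len` consecutive frames (zero-padded at field borders), then split
#' into three image streams with pairwise disjoint pixel supports: the target
#' cell's own pixels, the pixels of cells intersecting the target (minus the
#' target's), and everything else (neuropil). The streams sum exactly to the
#' raw patch. Intensities are normalized per patch by the 99.9th percentile
#' of the raw crop and clipped to `[0, 1]`, identically for all streams.
#'
#' @param movie `cacti_movie` or frames array.
#' @param cell_map a `cacti_cellmap`.
#' @param cell_id target cell.
#' @param start_frame 0-based first frame of the segment.
#' @param seq_len segment length in frames (default 100).
#' @param window square window size in pixels (default 25).
#' @param labels optional `cacti_labels`; attaches the per-frame label vector.
#' @param normalize divide by the patch's 99.9th percentile and clip.
#' @return a `cacti_patch`: arrays `stream_cell`, `stream_overlap`,
#'   `stream_neuropil` of shape `(seq_len, window, window)`, plus metadata.
#' @export
make_streams <- function(movie, cell_map = NULL, cell_id, start_frame,
                         seq_len = 100, window = 25, labels = NULL,
                         normalize = TRUE) {
  if (inherits(movie, "cacti_movie") && is.null(cell_map))
    cell_map <- movie$cell_map
  frames <- if (inherits(movie, "cacti_movie")) movie$frames else movie
  d <- dim(frames)
  if (start_frame < 0 || start_frame + seq_len > d[1])
    stop_config("make_streams: segment [%d, %d) outside movie of %d frames",
                start_frame, start_frame + seq_len, d[1])
  ids <- vapply(cell_map$contours, `[[`, integer(1), "cell_id")
  i <- match(cell_id, ids)
  if (is.na(i)) stop_config("make_streams: unknown cell_id %d", cell_id)
  ct <- cell_map$contours[[i]]
  ctr <- mask_centroid(ct$mask)
  if (ctr[1] < 0 || ctr[1] >= d[3] || ctr[2] < 0 || ctr[2] >= d[2])
    stop_config("make_streams: cell centroid outside the movie")
  half <- (window - 1L) %/% 2L
  xs <- (ctr[1] - half):(ctr[1] + window - 1L - half)
  ys <- (ctr[2] - half):(ctr[2] + window - 1L - half)
  # window-local masks (row = y, col = x within the crop)
  in_win <- function(px) {
    px[, 1] >= xs[1] & px[, 1] <= xs[window] &
      px[, 2] >= ys[1] & px[, 2] <= ys[window]
  }
  win_lin <- function(px) {
    px <- px[in_win(px), , drop = FALSE]
    (px[, 2] - ys[1] + 1L) + (px[, 1] - xs[1]) * window
  }
  g <- cell_map$overlap_graph
  nb_ids <- unique(c(g[g[, 1] == cell_id, 2], g[g[, 2] == cell_id, 1]))
  cell_lin <- win_lin(ct$mask)
  nb_lin <- unique(unlist(lapply(match(nb_ids, ids), function(j)
    win_lin(cell_map$contours[[j]]$mask))))
  nb_lin <- setdiff(nb_lin, cell_lin)
  mask_cell <- matrix(0, window, window); mask_cell[cell_lin] <- 1
  mask_olap <- matrix(0, window, window); mask_olap[nb_lin] <- 1
  mask_neuro <- 1 - mask_cell - mask_olap
  # crop with zero padding
  vx <- xs >= 0 & xs < d[3]; vy <- ys >= 0 & ys < d[2]
  raw <- array(0, dim = c(seq_len, window, window))
  tsel <- start_frame + seq_len(seq_len)          # 1-based frame indices
  raw[, which(vy), which(vx)] <- frames[tsel, ys[vy] + 1L, xs[vx] + 1L]
  if (normalize) {
    sc <- stats::quantile(raw, 0.999, names = FALSE)
    if (sc > 0) raw <- raw / sc
    raw[raw > 1] <- 1
    raw[raw < 0] <- 0
  }
  bcast <- function(m) aperm(array(m, dim = c(window, window, seq_len)), c(3, 1, 2))
  sample <- structure(list(
    cell_id = as.integer(cell_id), start_frame = as.integer(start_frame),
    seq_len = as.integer(seq_len), window = as.integer(window),
    stream_cell = raw * bcast(mask_cell),
    stream_overlap = raw * bcast(mask_olap),
    stream_neuropil = raw * bcast(mask_neuro),
    weight = 1), class = "cacti_patch")
  if (!is.null(labels)) {
    r <- labels_to_raster(labels)
    row <- match(cell_id, labels$cell_ids)
    if (is.na(row)) stop_config("make_streams: cell %d absent from labels", cell_id)
    sample$label <- as.numeric(r[row, tsel])
  }
  sample
}

#' Segment start frames under a sliding window
#'
#' @param n_frames movie length.
#' @param seq_len segment length (default 100).
#' @param stride sliding-window step (default 10).
#' @return integer vector of 0-based start frames
#'   (`0, stride, ...` while `start + seq_len <= n_frames`).
#' @export
temporal_segments <- function(n_frames, seq_len = 100, stride = 10) {
  if (n_frames < seq_len)
    stop_config("temporal_segments: n_frames (%d) < seq_len (%d)",
                n_frames, seq_len)
  seq.int(0L, n_frames - seq_len, by = stride)
}

#' Apply a spatial augmentation to a patch sample
#'
#' The same transform is applied to every frame of all three streams; label
#' vectors are temporal and unchanged. Only exact pixel-lattice transforms
#' are offered (flips, 90-degree rotations, integer translations), which
#' preserve the disjoint-support partition exactly.
#'
#' @param sample a `cacti_patch`.
#' @param op one of `"flip_h"`, `"flip_v"`, `"rot90"`, `"translate"`.
#' @param k quarter turns for `"rot90"` (default 1).
#' @param dx,dy integer pixel shifts for `"translate"` (|dx|,|dy| <= 5).
#' @return the transformed `cacti_patch`.
#' @export
augment_spatial <- function(sample, op = c("flip_h", "flip_v", "rot90",
                                           "translate"),
                            k = 1L, dx = 0L, dy = 0L) {
  op <- match.arg(op)
  w <- sample$window
  tx <- function(a) {
    out <- a
    for (t in seq_len(dim(a)[1])) {
      m <- a[t, , ]
      m <- switch(op,
        flip_h = m[, w:1],
        flip_v = m[w:1, ],
        rot90 = { r <- m; for (i in seq_len(((k %% 4) + 4) %% 4))
                    r <- t(r)[w:1, ]; r },
        translate = {
          r <- matrix(0, w, w)
          sr <- seq_len(w) - dy; sc <- seq_len(w) - dx
          ok_r <- sr >= 1 & sr <= w; ok_c <- sc >= 1 & sc <= w
          r[which(ok_r), which(ok_c)] <- m[sr[ok_r], sc[ok_c]]
          r
        })
      out[t, , ] <- m
    }
    out
  }
  if (op == "translate" && (abs(dx) > 5 || abs(dy) > 5))
    stop_config("augment_spatial: translation limited to 5 px")
  out <- sample
  out$stream_cell <- tx(sample$stream_cell)
  out$stream_overlap <- tx(sample$stream_overlap)
  out$stream_neuropil <- tx(sample$stream_neuropil)
  if (op == "translate" && sum(out$stream_cell != 0) == 0 &&
      sum(sample$stream_cell != 0) > 0)
    stop_config("augment_spatial: translation pushed the cell out of the window")
  out
}

#' Classify a movie segment by its transient content
#'
#' `REAL` if any ground-truth interval of the cell intersects the segment;
#' else `FAKE_ONLY` if any putative-but-unlabeled rise intersects it; else
#' `EMPTY`. A putative rise counts as fake when it does not intersect any
#' ground-truth interval (extended by `slack` frames to absorb edge effects).
#'
#' @param labels ground-truth `cacti_labels`.
#' @param putative putative-transient `cacti_labels` (e.g. from
#'   [detect_putative_transients_movie()]).
#' @param cell_id target cell.
#' @param start_frame,seq_len segment, 0-based.
#' @param slack tolerance in frames when matching putative to real (default 2).
#' @return one of `"REAL"`, `"FAKE_ONLY"`, `"EMPTY"`.
#' @export
classify_segment <- function(labels, putative, cell_id, start_frame,
                             seq_len = 100, slack = 2) {
  s0 <- start_frame; s1 <- start_frame + seq_len - 1L
  gt <- labels$intervals[[match(cell_id, labels$cell_ids)]]
  if (is.null(gt)) stop_config("classify_segment: cell %d not in labels", cell_id)
  if (nrow(gt) && any(intervals_intersect(gt[, 1], gt[, 2], s0, s1)))
    return("REAL")
  pt <- putative$intervals[[match(cell_id, putative$cell_ids)]]
  if (!is.null(pt) && nrow(pt)) {
    fake <- vapply(seq_len(nrow(pt)), function(k) {
      !nrow(gt) || !any(intervals_intersect(gt[, 1] - slack, gt[, 2] + slack,
                                            pt[k, 1], pt[k, 2]))
    }, logical(1))
    if (any(fake & intervals_intersect(pt[, 1], pt[, 2], s0, s1)))
      return("FAKE_ONLY")
  }
  "EMPTY"
}

#' Stratify segments to target class proportions
#'
#' Over-represented classes are uniformly subsampled; under-represented
#' classes reach their quota by replicating members (replicates are flagged
#' `augment = TRUE` so the training loop applies a random spatial
#' augmentation to them). Segments containing fake transients get weight
#' `w_fake`; the others weight 1.
#'
#' @param classes character vector of segment classes
#'   (`"REAL"`, `"FAKE_ONLY"`, `"EMPTY"`).
#' @param target numeric(3) proportions for (REAL, FAKE_ONLY, EMPTY),
#'   default `c(0.60, 0.30, 0.10)`.
#' @param n_out output pool size (default = input size).
#' @param w_fake weight for FAKE_ONLY segments (default 5).
#' @param seed integer RNG seed.
#' @return data frame with columns `index` (into the input), `class`,
#'   `weight`, `augment`.
#' @export
stratify <- function(classes, target = c(0.60, 0.30, 0.10),
                     n_out = length(classes), w_fake = 5, seed = NULL) {
  lv <- c("REAL", "FAKE_ONLY", "EMPTY")
  if (!all(classes %in% lv))
    stop_config("stratify: unknown class %s",
                paste(unique(setdiff(classes, lv)), collapse = ", "))
  miss <- lv[!(lv %in% classes)]
  if (length(miss))
    stop_config("stratify: no segments of class %s", paste(miss, collapse = ", "))
  if (abs(sum(target) - 1) > 1e-8) stop_config("stratify: target must sum to 1")
  quota <- round(n_out * target)
  quota[1] <- n_out - sum(quota[-1])   # keep the total exact
  with_seed(seed, {
    pick <- function(pool, k, replace = FALSE)
      pool[sample.int(length(pool), k, replace = replace)]
    picks <- lapply(seq_along(lv), function(ci) {
      pool <- which(classes == lv[ci])
      q <- quota[ci]
      if (q <= length(pool)) {
        idx <- pick(pool, q)
        data.frame(index = idx, augment = rep(FALSE, length(idx)))
      } else {
        extra <- pick(pool, q - length(pool), replace = TRUE)
        data.frame(index = c(pool, extra),
                   augment = c(rep(FALSE, length(pool)),
                               rep(TRUE, length(extra))))
      }
    })
    out <- do.call(rbind, Map(function(p, cl) {
      p$class <- cl; p
    }, picks, lv))
    out$weight <- ifelse(out$class == "FAKE_ONLY", w_fake, 1)
    out <- out[sample.int(nrow(out)), c("index", "class", "weight", "augment")]
    rownames(out) <- NULL
    out
  })
}

#' Split samples into training and validation sets by cell
#'
#' All segments of a cell land on the same side, preventing temporal leakage
#' between training and validation.
#'
#' @param cell_ids integer vector, one entry per sample.
#' @param ratio training fraction (default 0.8).
#' @param seed integer RNG seed.
#' @return list with logical vector `train` (TRUE = training sample) and the
#'   cell id sets `train_cells`, `val_cells`.
#' @export
split_train_validation <- function(cell_ids, ratio = 0.8, seed = NULL) {
  cells <- unique(cell_ids)
  if (length(cells) < 2)
    stop_config("split: need at least 2 distinct cells, got %d", length(cells))
  if (length(cell_ids) < 5)
    stop_config("split: need at least 5 samples")
  with_seed(seed, {
    n_train <- max(1L, min(length(cells) - 1L, round(ratio * length(cells))))
    train_cells <- sample(cells, n_train)
    list(train = cell_ids %in% train_cells,
         train_cells = sort(train_cells),
         val_cells = sort(setdiff(cells, train_cells)))
  })
}
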