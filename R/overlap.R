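# Overlap-induced false-transient detection: pairs of cells sharing enough
# footprint, spatial source/transient profiles, and correlation verdicts.

#' Find pairs of cells with substantial footprint overlap
#'
#' The shared-area fraction is the intersection size divided by the larger
#' of the two masks; pairs at or above `min_fraction` (default 15%) are the
#' ones where a true transient in one cell can trigger a false transient in
#' the other.
#'
#' @param cell_map a `cacti_cellmap`.
#' @param min_fraction minimal shared-area fraction (default 0.15).
#' @return data frame with `cell_a`, `cell_b`, `shared_area_fraction`.
#' @export
find_overlap_pairs <- function(cell_map, min_fraction = 0.15) {
  cts <- cell_map$contours
  w <- cell_map$field_shape[2]
  out <- data.frame(cell_a = integer(0), cell_b = integer(0),
                    shared_area_fraction = numeric(0))
  n <- length(cts)
  if (n < 2) return(out)
  keys <- lapply(cts, function(ct) pixel_key(ct$mask, w))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    inter <- sum(keys[[i]] %in% keys[[j]])
    if (inter == 0) next
    frac <- inter / max(length(keys[[i]]), length(keys[[j]]))
    if (frac >= min_fraction)
      out <- rbind(out, data.frame(cell_a = cts[[i]]$cell_id,
                                   cell_b = cts[[j]]$cell_id,
                                   shared_area_fraction = frac))
  }
  out
}

# Crop a full-field image to a window: list(xs, ys) of 0-based coords.
crop_image <- function(img, xs, ys) img[ys + 1L, xs + 1L, drop = FALSE]

# Bounding window of the union of two masks, padded, clipped to the field.
pair_window <- function(ct_a, ct_b, field_shape, pad = 3L) {
  px <- rbind(ct_a$mask, ct_b$mask)
  xs <- max(0L, min(px[, 1]) - pad):min(field_shape[2] - 1L, max(px[, 1]) + pad)
  ys <- max(0L, min(px[, 2]) - pad):min(field_shape[1] - 1L, max(px[, 2]) + pad)
  list(xs = xs, ys = ys)
}

#' Spatial profile of one putative transient
#'
#' The mean of the frames over `[onset + 1, peak]` minus the onset frame: the
#' spatial fingerprint of where the fluorescence rise happened.
#'
#' @param frames numeric array `(n_frames, h, w)` or `cacti_movie`.
#' @param onset,peak 0-based inclusive rise interval; the rise must span at
#'   least one frame (`peak > onset`).
#' @return matrix `(h, w)` (full field; crop as needed).
#' @export
transient_profile <- function(frames, onset, peak) {
  if (inherits(frames, "cacti_movie")) frames <- frames$frames
  d <- dim(frames)
  if (peak <= onset) stop_config("transient_profile: rise of length 0")
  if (onset < 0 || peak >= d[1])
    stop_config("transient_profile: rise outside the movie")
  rise <- (onset + 1L):peak
  prof <- apply(frames[rise, , , drop = FALSE], c(2, 3), mean)
  prof - frames[onset + 1L, , ]
}

#' Source profile of a cell
#'
#' The cell's spatial fingerprint: for each putative transient, the frames
#' around the peak (`[peak - 1, peak + 1]`, clipped to the movie) minus the
#' onset frame, averaged across all the cell's transients.
#'
#' @param frames numeric array or `cacti_movie`.
#' @param labels a `cacti_labels` holding the cell's putative transients.
#' @param cell_id which cell.
#' @return matrix `(h, w)`.
#' @export
source_profile <- function(frames, labels, cell_id) {
  if (inherits(frames, "cacti_movie")) frames <- frames$frames
  d <- dim(frames)
  iv <- labels$intervals[[match(cell_id, labels$cell_ids)]]
  if (is.null(iv) || nrow(iv) == 0)
    stop_config("source_profile: cell %d has no transients", cell_id)
  acc <- matrix(0, d[2], d[3])
  for (k in seq_len(nrow(iv))) {
    pk <- iv[k, 2]
    fr <- max(0L, pk - 1L):min(d[1] - 1L, pk + 1L)
    m <- apply(frames[fr + 1L, , , drop = FALSE], c(2, 3), mean)
    acc <- acc + (m - frames[iv[k, 1] + 1L, , ])
  }
  acc / nrow(iv)
}

# Pearson correlation over a cropped window; zero-variance input is an error.
profile_correlation <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_config("profile correlation: zero-variance profile")
  stats::cor(as.vector(a), as.vector(b))
}

#' Detect overlap-induced false transients
#'
#' For every overlapping pair (shared area >= `min_fraction`) and every pair
#' of co-timed putative rises (intervals overlapping by >= 1 frame), the
#' spatial profile of each rise is correlated with both cells' source
#' profiles over the pair's cropped window. If the profile of cell B's rise
#' correlates strongly with A's source (`>= r_high`) and weakly with B's own
#' (`<= r_low`), B's rise is a false transient driven by A's activity (and
#' symmetrically). Conflicting verdicts degrade to UNCLASSIFIED.
#'
#' @param movie `cacti_movie` or frames array.
#' @param cell_map a `cacti_cellmap`.
#' @param putative a `cacti_labels` of putative rises per cell.
#' @param r_high correlation threshold for the truly active cell (0.7).
#' @param r_low correlation threshold for the passive cell (0.2).
#' @param min_fraction overlap fraction defining eligible pairs (0.15).
#' @return data frame with `cell_id`, `onset`, `peak`, `verdict`
#'   (`"FALSE_TRANSIENT"` or `"UNCLASSIFIED"`), `source_cell` (the cell whose
#'   activity explains the rise, NA when unclassified), and the two
#'   correlations.
#' @export
detect_false_transients <- function(movie, cell_map = NULL, putative,
                                    r_high = 0.7, r_low = 0.2,
                                    min_fraction = 0.15) {
  if (inherits(movie, "cacti_movie") && is.null(cell_map))
    cell_map <- movie$cell_map
  frames <- if (inherits(movie, "cacti_movie")) movie$frames else movie
  pairs <- find_overlap_pairs(cell_map, min_fraction)
  verdicts <- data.frame(cell_id = integer(0), onset = integer(0),
                         peak = integer(0), verdict = character(0),
                         source_cell = integer(0), r_self = numeric(0),
                         r_other = numeric(0))
  if (nrow(pairs) == 0) return(verdicts)
  ids <- vapply(cell_map$contours, `[[`, integer(1), "cell_id")
  add <- function(df, cell, on, pk, verdict, src, r_self, r_other) {
    rbind(df, data.frame(cell_id = cell, onset = on, peak = pk,
                         verdict = verdict, source_cell = src,
                         r_self = r_self, r_other = r_other))
  }
  for (p in seq_len(nrow(pairs))) {
    ia <- match(pairs$cell_a[p], ids); ib <- match(pairs$cell_b[p], ids)
    ct_a <- cell_map$contours[[ia]]; ct_b <- cell_map$contours[[ib]]
    win <- pair_window(ct_a, ct_b, cell_map$field_shape)
    iv_a <- putative$intervals[[match(ct_a$cell_id, putative$cell_ids)]]
    iv_b <- putative$intervals[[match(ct_b$cell_id, putative$cell_ids)]]
    if (is.null(iv_a) || is.null(iv_b) || !nrow(iv_a) || !nrow(iv_b)) next
    src_a <- crop_image(source_profile(frames, putative, ct_a$cell_id),
                        win$xs, win$ys)
    src_b <- crop_image(source_profile(frames, putative, ct_b$cell_id),
                        win$xs, win$ys)
    for (ka in seq_len(nrow(iv_a))) for (kb in seq_len(nrow(iv_b))) {
      if (!intervals_intersect(iv_a[ka, 1], iv_a[ka, 2],
                               iv_b[kb, 1], iv_b[kb, 2])) next
      judge <- function(on, pk) {
        if (pk <= on) return(c(NA_real_, NA_real_))
        prof <- crop_image(transient_profile(frames, on, pk), win$xs, win$ys)
        c(profile_correlation(prof, src_a), profile_correlation(prof, src_b))
      }
      r_evt_a <- judge(iv_a[ka, 1], iv_a[ka, 2])
      r_evt_b <- judge(iv_b[kb, 1], iv_b[kb, 2])
      # B's rise is false when the event points to A, and vice versa
      b_false <- isTRUE(r_evt_b[1] >= r_high && r_evt_b[2] <= r_low)
      a_false <- isTRUE(r_evt_a[2] >= r_high && r_evt_a[1] <= r_low)
      if (b_false && !a_false)
        verdicts <- add(verdicts, ct_b$cell_id, iv_b[kb, 1], iv_b[kb, 2],
                        "FALSE_TRANSIENT", ct_a$cell_id,
                        r_evt_b[2], r_evt_b[1])
      else if (a_false && !b_false)
        verdicts <- add(verdicts, ct_a$cell_id, iv_a[ka, 1], iv_a[ka, 2],
                        "FALSE_TRANSIENT", ct_b$cell_id,
                        r_evt_a[1], r_evt_a[2])
      else
        verdicts <- add(verdicts, ct_b$cell_id, iv_b[kb, 1], iv_b[kb, 2],
                        "UNCLASSIFIED", NA_integer_, r_evt_b[2], r_evt_b[1])
    }
  }
  if (nrow(verdicts)) {
    # a transient keeps at most one FALSE verdict; conflicts -> UNCLASSIFIED
    key <- paste(verdicts$cell_id, verdicts$onset, verdicts$peak)
    for (k in unique(key)) {
      rows <- which(key == k)
      f <- rows[verdicts$verdict[rows] == "FALSE_TRANSIENT"]
      if (length(f) > 1 &&
          length(unique(verdicts$source_cell[f])) > 1) {
        verdicts$verdict[f] <- "UNCLASSIFIED"
        verdicts$source_cell[f] <- NA_integer_
      }
    }
    verdicts <- verdicts[!duplicated(paste(key, verdicts$verdict,
                                           verdicts$source_cell)), ]
    rownames(verdicts) <- NULL
  }
  verdicts
}

#' Audit how a classifier handles known false transients
#'
#' A false transient counts as correctly rejected when the maximal predicted
#' activation probability over its rise stays below the threshold.
#'
#' @param false_transients data frame with `cell_id`, `onset`, `peak` (e.g.
#'   the FALSE_TRANSIENT rows of [detect_false_transients()]).
#' @param predictions a `cacti_predictions`.
#' @param threshold rejection threshold (default 0.5).
#' @return list with `fraction_rejected`, `n_rejected`, `n_total`;
#'   `fraction_rejected` is `NA` when there is nothing to audit.
#' @export
audit_classifier <- function(false_transients, predictions, threshold = 0.5) {
  n <- nrow(false_transients)
  if (is.null(n) || n == 0)
    return(list(fraction_rejected = NA_real_, n_rejected = 0L, n_total = 0L))
  rejected <- 0L
  for (k in seq_len(n)) {
    row <- match(false_transients$cell_id[k], predictions$cell_ids)
    if (is.na(row))
      stop_config("audit: no predictions for cell %d",
                  false_transients$cell_id[k])
    fr <- (false_transients$onset[k]:false_transients$peak[k]) + 1L
    if (max(predictions$prob[row, fr]) < threshold) rejected <- rejected + 1L
  }
  list(fraction_rejected = rejected / n, n_rejected = rejected, n_total = n)
}
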