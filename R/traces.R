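# Fluorescence trace extraction and putative-transient detection.

#' Extract a cell's fluorescence trace from a movie
#'
#' `raw` is the per-frame mean intensity over the cell's mask pixels. `dff`
#' is (F - F0) / F0 with F0 the 8th percentile of the raw trace over a
#' sliding window (robust to transients); for movies shorter than the window
#' the global 8th percentile is used.
#'
#' @param frames numeric array `(n_frames, height, width)` or `cacti_movie`.
#' @param contour a `cacti_contour` placed in movie coordinates.
#' @param mode `"raw"` or `"dff"`.
#' @param f0_window sliding-window width in frames for the dff baseline.
#' @param f0_quantile baseline quantile (default 0.08).
#' @return numeric vector of length `n_frames`.
#' @export
extract_trace <- function(frames, contour, mode = c("raw", "dff"),
                          f0_window = 1000, f0_quantile = 0.08) {
  mode <- match.arg(mode)
  if (inherits(frames, "cacti_movie")) frames <- frames$frames
  d <- dim(frames)
  if (nrow(contour$mask) == 0) stop_config("extract_trace: empty mask")
  if (any(contour$mask[, 1] < 0 | contour$mask[, 1] >= d[3] |
          contour$mask[, 2] < 0 | contour$mask[, 2] >= d[2]))
    stop_config("extract_trace: mask outside movie bounds")
  # linear indices into a (h, w) frame for the mask pixels
  lin <- contour$mask[, 2] + 1L + contour$mask[, 1] * d[2]
  flat <- matrix(frames, nrow = d[1])          # n_frames x (h*w)
  raw <- rowMeans(flat[, lin, drop = FALSE])
  if (mode == "raw") return(raw)
  if (length(raw) <= f0_window) {
    f0 <- rep(stats::quantile(raw, f0_quantile, names = FALSE), length(raw))
  } else {
    f0 <- zoo::rollapply(raw, width = f0_window,
                         FUN = stats::quantile, probs = f0_quantile,
                         names = FALSE, fill = NA, partial = TRUE,
                         align = "center")
  }
  if (any(f0 <= 0)) stop_config("extract_trace: non-positive dff baseline F0")
  (raw - f0) / f0
}

#' Detect putative calcium transients on a fluorescence trace
#'
#' The trace is smoothed with a centered moving average; local maxima whose
#' prominence over the preceding local minimum exceeds the threshold become
#' candidate peaks, and the onset of each candidate is the last local minimum
#' before the peak. The default prominence is `3 x mad(diff(trace))`, scaling
#' the threshold with the frame-to-frame noise.
#'
#' @param trace numeric vector (raw or dff fluorescence).
#' @param smooth_width moving-average width in frames (odd, default 5).
#' @param prominence absolute prominence threshold; `NULL` for the default.
#' @param cell_id id attached to the returned labels.
#' @return a `cacti_labels` with one cell holding the candidate
#'   (onset, peak) intervals (possibly none).
#' @export
detect_putative_transients <- function(trace, smooth_width = 5,
                                       prominence = NULL, cell_id = 1L) {
  if (any(!is.finite(trace))) stop_config("putative transients: non-finite trace")
  n <- length(trace)
  if (is.null(prominence))
    prominence <- 3 * stats::mad(diff(trace))
  sm <- as.numeric(stats::filter(trace, rep(1 / smooth_width, smooth_width),
                                 sides = 2))
  # pad the ends with the raw values the filter left NA
  na <- is.na(sm)
  sm[na] <- trace[na]
  d <- diff(sm)
  # local extrema on the smoothed trace (plateau-safe via sign changes)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo::na.locf(s, na.rm = FALSE)
  s[is.na(s)] <- 1
  turn <- diff(s)
  peaks <- which(turn < 0) + 1L
  mins <- c(1L, which(turn > 0) + 1L, n)
  ivs <- NULL
  for (p in peaks) {
    prev_min <- max(mins[mins < p])
    if (sm[p] - sm[prev_min] >= prominence) {
      ivs <- rbind(ivs, c(prev_min - 1L, p - 1L))   # 0-based inclusive
    }
  }
  if (!is.null(ivs)) ivs <- merge_intervals(ivs)
  new_labels(list(ivs), cell_ids = cell_id, n_frames = n)
}

#' Putative transients for every cell of a movie
#' @param movie `cacti_movie` or frames array.
#' @param cell_map a `cacti_cellmap`.
#' @param mode trace mode passed to [extract_trace()].
#' @param ... passed to [detect_putative_transients()].
#' @return a `cacti_labels` over all cells.
#' @export
detect_putative_transients_movie <- function(movie, cell_map = NULL,
                                             mode = "raw", ...) {
  if (inherits(movie, "cacti_movie") && is.null(cell_map))
    cell_map <- movie$cell_map
  frames <- if (inherits(movie, "cacti_movie")) movie$frames else movie
  ids <- vapply(cell_map$contours, `[[`, integer(1), "cell_id")
  ivs <- lapply(cell_map$contours, function(ct) {
    tr <- extract_trace(frames, ct, mode = mode)
    detect_putative_transients(tr, cell_id = ct$cell_id, ...)$intervals[[1]]
  })
  new_labels(ivs, ids, dim(frames)[1])
}
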