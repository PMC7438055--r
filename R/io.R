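# Shared data model: labels, rasters, contour sets, prediction traces, and
# the plain-text readers/writers. All files are 0-based (declared in their
# headers); intervals are inclusive [onset, peak].

# Merge overlapping or touching inclusive intervals; input m: 2-col matrix.
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "peak"))))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2] + 0L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  colnames(out) <- c("onset", "peak")
  out
}

#' Construct an activity-labels object
#'
#' @param intervals list (one element per cell) of two-column matrices of
#'   inclusive `(onset, peak)` frame intervals, 0-based.
#' @param cell_ids integer ids, unique, same length as `intervals`.
#' @param n_frames total movie length.
#' @return a `cacti_labels` object.
#' @export
new_labels <- function(intervals, cell_ids, n_frames) {
  if (length(intervals) != length(cell_ids))
    stop_config("labels: intervals and cell_ids lengths differ")
  if (anyDuplicated(cell_ids)) stop_config("labels: duplicate cell_ids")
  intervals <- lapply(intervals, function(m) {
    if (is.null(m) || nrow(m) == 0)
      return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "peak"))))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[, 2] < m[, 1])) stop_config("labels: peak < onset")
    if (any(m[, 1] < 0) || any(m[, 2] >= n_frames))
      stop_config("labels: interval outside [0, n_frames)")
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop_config("labels: overlapping intervals within a cell")
    colnames(m) <- c("onset", "peak")
    m
  })
  structure(list(intervals = intervals, cell_ids = as.integer(cell_ids),
                 n_frames = as.integer(n_frames)),
            class = "cacti_labels")
}

#' @export
print.cacti_labels <- function(x, ...) {
  cat(sprintf("<cacti_labels> %d cells, %d frames, %d transients\n",
              length(x$cell_ids), x$n_frames,
              sum(vapply(x$intervals, nrow, integer(1)))))
  invisible(x)
}

#' Expand labels to a cells x frames binary raster
#'
#' A cell is active on every frame of each inclusive `[onset, peak]` interval
#' (the rise time, which defines "active").
#'
#' @param labels a `cacti_labels`.
#' @return logical matrix `n_cells x n_frames` with cell_ids as rownames.
#' @export
labels_to_raster <- function(labels) {
  stopifnot(inherits(labels, "cacti_labels"))
  r <- matrix(FALSE, length(labels$cell_ids), labels$n_frames)
  for (i in seq_along(labels$intervals)) {
    m <- labels$intervals[[i]]
    for (k in seq_len(nrow(m))) r[i, (m[k, 1]:m[k, 2]) + 1L] <- TRUE
  }
  rownames(r) <- labels$cell_ids
  r
}

#' Collapse a binary raster back to (onset, peak) intervals
#'
#' Maximal runs of TRUE become inclusive intervals; inverse of
#' [labels_to_raster()] on well-formed rasters.
#'
#' @param raster logical matrix `n_cells x n_frames`.
#' @param cell_ids optional ids (default from rownames or 1..n).
#' @return a `cacti_labels`.
#' @export
raster_to_labels <- function(raster, cell_ids = NULL) {
  if (!is.matrix(raster)) raster <- matrix(raster, nrow = 1)
  if (is.null(cell_ids))
    cell_ids <- if (!is.null(rownames(raster))) as.integer(rownames(raster))
      else seq_len(nrow(raster))
  ivs <- lapply(seq_len(nrow(raster)), function(i) {
    rl <- rle(as.logical(raster[i, ]))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    cbind(onset = starts[keep] - 1L, peak = ends[keep] - 1L)
  })
  new_labels(ivs, cell_ids, ncol(raster))
}

#' Construct a prediction-trace object
#' @param prob numeric matrix `n_cells x n_frames` of activation
#'   probabilities in `[0, 1]`.
#' @param cell_ids integer ids.
#' @param threshold activation threshold (default 0.5).
#' @export
new_predictions <- function(prob, cell_ids = seq_len(nrow(prob)),
                            threshold = 0.5) {
  if (!is.matrix(prob)) prob <- matrix(prob, nrow = 1)
  if (any(prob < 0 | prob > 1 | !is.finite(prob)))
    stop_config("predictions: probabilities must be finite and in [0, 1]")
  if (anyDuplicated(cell_ids)) stop_config("predictions: duplicate cell_ids")
  rownames(prob) <- cell_ids
  structure(list(prob = prob, cell_ids = as.integer(cell_ids),
                 threshold = threshold),
            class = "cacti_predictions")
}

# ---- movie files -----------------------------------------------------------

#' Write a frame stack as a 16-bit multi-page TIFF
#'
#' Intensities are affinely scaled to the 16-bit range; the scaling (and any
#' extra key-value pairs) is recorded in a plain-text metadata file so reads
#' can restore the original units up to quantization.
#'
#' @param frames numeric array `(n_frames, height, width)`.
#' @param path output TIFF path.
#' @param meta_path metadata path (default `<path>.meta.txt`).
#' @param extra_meta named character/numeric vector of additional metadata.
#' @export
write_movie <- function(frames, path, meta_path = paste0(path, ".meta.txt"),
                        extra_meta = NULL) {
  if (length(dim(frames)) != 3 || dim(frames)[1] < 1)
    stop_config("write_movie: frames must be a non-empty (t, h, w) array")
  lo <- min(frames); hi <- max(frames)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(frames)[1]),
                  function(t) (frames[t, , ] - lo) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(intensity_min = lo, intensity_span = span,
            n_frames = dim(frames)[1], height = dim(frames)[2],
            width = dim(frames)[3], extra_meta)
  writeLines(paste(names(meta), meta, sep = "\t"), meta_path)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#' @param path TIFF path.
#' @param meta_path metadata path (default `<path>.meta.txt`).
#' @return numeric array `(n_frames, height, width)` in original units.
#' @export
read_movie <- function(path, meta_path = paste0(path, ".meta.txt")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop_config("read_movie: %s has zero frames", path)
  lo <- 0; span <- 1
  if (file.exists(meta_path)) {
    kv <- utils::read.delim(meta_path, header = FALSE,
                            col.names = c("key", "value"),
                            stringsAsFactors = FALSE)
    lo <- as.numeric(kv$value[kv$key == "intensity_min"]) %||% 0
    span <- as.numeric(kv$value[kv$key == "intensity_span"]) %||% 1
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * span + lo
  frames
}

# ---- contour files ---------------------------------------------------------

#' Write a contour set as columnar text
#'
#' Columns: cell_id, vertex_index, x, y (0-based pixel coordinates).
#' @param cell_map a `cacti_cellmap` (or list with `contours`, `field_shape`).
#' @param path output CSV path.
#' @export
write_contours <- function(cell_map, path) {
  rows <- do.call(rbind, lapply(cell_map$contours, function(ct) {
    data.frame(cell_id = ct$cell_id,
               vertex_index = seq_len(nrow(ct$polygon)) - 1L,
               x = ct$polygon[, 1], y = ct$polygon[, 2])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_height=%d field_width=%d coords=0-based",
                     cell_map$field_shape[1], cell_map$field_shape[2]), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contour set written by [write_contours()]
#'
#' Polygons are re-rasterized to pixel masks; the soma/nucleus partition uses
#' the same concentric-nucleus convention as the simulator.
#' @param path CSV path.
#' @param nucleus_scale linear scale of the concentric nucleus polygon.
#' @return a `cacti_cellmap` (overlap graph recomputed from pixel masks).
#' @export
read_contours <- function(path, nucleus_scale = 0.5) {
  header <- readLines(path, n = 1)
  fs <- c(100L, 100L)
  m <- regmatches(header, regexec("field_height=(\\d+) field_width=(\\d+)", header))[[1]]
  if (length(m) == 3) fs <- as.integer(m[2:3])
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "vertex_index", "x", "y")
  if (!all(need %in% names(d)))
    stop_config("read_contours: %s lacks columns %s", path,
                paste(setdiff(need, names(d)), collapse = ", "))
  contours <- lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$vertex_index), ]
    poly <- cbind(g$x, g$y)
    ctr <- colMeans(poly)
    mask <- rasterize_polygon(poly)
    if (nrow(mask) == 0)
      stop_config("read_contours: cell %d rasterizes to an empty mask",
                  g$cell_id[1])
    nuc_poly <- sweep(sweep(poly, 2, ctr), 2, rep(nucleus_scale, 2), `*`)
    nuc_poly <- sweep(nuc_poly, 2, ctr, `+`)
    nuc <- rasterize_polygon(nuc_poly)
    keys <- pixel_key(mask, 4096L)
    nuc <- nuc[pixel_key(nuc, 4096L) %in% keys, , drop = FALSE]
    soma <- mask[!(keys %in% pixel_key(nuc, 4096L)), , drop = FALSE]
    structure(list(cell_id = g$cell_id[1], polygon = poly, mask = mask,
                   nucleus_mask = nuc, soma_mask = soma,
                   center = round(ctr)),
              class = "cacti_contour")
  })
  contours <- contours[order(vapply(contours, `[[`, numeric(1), "cell_id"))]
  for (ct in contours) {
    if (any(ct$mask[, 1] < 0 | ct$mask[, 1] >= fs[2] |
            ct$mask[, 2] < 0 | ct$mask[, 2] >= fs[1]))
      stop_config("read_contours: cell %d mask outside the %dx%d field",
                  ct$cell_id, fs[1], fs[2])
  }
  structure(list(contours = unname(contours), field_shape = fs,
                 overlap_graph = overlap_graph(contours, fs[2])),
            class = "cacti_cellmap")
}

# ---- label files -----------------------------------------------------------

#' Write activity labels as columnar text (cell_id, onset_frame, peak_frame)
#' @param labels a `cacti_labels`.
#' @param path output CSV path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "cacti_labels"))
  rows <- do.call(rbind, lapply(seq_along(labels$cell_ids), function(i) {
    m <- labels$intervals[[i]]
    if (nrow(m) == 0) return(NULL)
    data.frame(cell_id = labels$cell_ids[i], onset_frame = m[, 1],
               peak_frame = m[, 2])
  }))
  if (is.null(rows))
    rows <- data.frame(cell_id = integer(0), onset_frame = integer(0),
                       peak_frame = integer(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_frames=%d cells=%s frames=0-based", labels$n_frames,
                     paste(labels$cell_ids, collapse = ";")), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read activity labels written by [write_labels()]
#' @param path CSV path.
#' @param n_frames override movie length (default from file header).
#' @return a `cacti_labels`.
#' @export
read_labels <- function(path, n_frames = NULL) {
  header <- readLines(path, n = 1)
  hm <- regmatches(header, regexec("n_frames=(\\d+) cells=([0-9;]*)", header))[[1]]
  if (is.null(n_frames)) {
    if (length(hm) < 2) stop_config("read_labels: %s lacks n_frames header", path)
    n_frames <- as.integer(hm[2])
  }
  cells <- if (length(hm) == 3 && nzchar(hm[3]))
    as.integer(strsplit(hm[3], ";")[[1]]) else integer(0)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "onset_frame", "peak_frame")
  if (!all(need %in% names(d)))
    stop_config("read_labels: %s lacks columns %s", path,
                paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(d$peak_frame < d$onset_frame)
  if (length(bad))
    stop_config("read_labels: peak < onset at data row %d of %s", bad[1], path)
  bad <- which(d$onset_frame < 0 | d$peak_frame >= n_frames)
  if (length(bad))
    stop_config("read_labels: frame out of [0, %d) at data row %d of %s",
                n_frames, bad[1], path)
  cell_ids <- sort(unique(c(cells, d$cell_id)))
  ivs <- lapply(cell_ids, function(id) {
    g <- d[d$cell_id == id, , drop = FALSE]
    cbind(onset = as.integer(g$onset_frame), peak = as.integer(g$peak_frame))
  })
  new_labels(ivs, cell_ids, n_frames)
}

# ---- prediction files ------------------------------------------------------

#' Write prediction traces (cell_id, frame, probability), 6 decimals
#' @param predictions a `cacti_predictions`.
#' @param path output CSV path.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(inherits(predictions, "cacti_predictions"))
  p <- predictions$prob
  rows <- data.frame(
    cell_id = rep(predictions$cell_ids, each = ncol(p)),
    frame = rep(seq_len(ncol(p)) - 1L, times = nrow(p)),
    probability = sprintf("%.6f", as.vector(t(p))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_frames=%d frames=0-based threshold=%g", ncol(p),
                     predictions$threshold), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prediction traces written by [write_predictions()]
#' @param path CSV path.
#' @return a `cacti_predictions`.
#' @export
read_predictions <- function(path) {
  header <- readLines(path, n = 1)
  thr <- 0.5
  hm <- regmatches(header, regexec("threshold=([0-9.]+)", header))[[1]]
  if (length(hm) == 2) thr <- as.numeric(hm[2])
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "probability")
  if (!all(need %in% names(d)))
    stop_config("read_predictions: %s lacks columns %s", path,
                paste(setdiff(need, names(d)), collapse = ", "))
  bad <- which(d$probability < 0 | d$probability > 1)
  if (length(bad))
    stop_config("read_predictions: probability outside [0,1] at data row %d",
                bad[1])
  ids <- sort(unique(d$cell_id))
  nf <- max(d$frame) + 1L
  prob <- matrix(0, length(ids), nf)
  for (i in seq_along(ids)) {
    g <- d[d$cell_id == ids[i], ]
    if (nrow(g) != nf || anyDuplicated(g$frame))
      stop_config("read_predictions: cell %d has %d rows for %d frames",
                  ids[i], nrow(g), nf)
    prob[i, g$frame + 1L] <- g$probability
  }
  new_predictions(prob, ids, threshold = thr)
}
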