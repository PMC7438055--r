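#' Render a simulated calcium-imaging movie
#'
#' Every pixel value is
#' `baseline(px) + sum over cells of gain(px, cell) * trace_cell(t) + N(mu, sigma2)`,
#' where the gain is `soma_gain` for soma pixels and `nucleus_gain` for
#' nucleus pixels (fluorescence is lower in the nucleus), overlapping cells'
#' contributions add, and the additive noise is i.i.d. Gaussian per pixel and
#' frame. The baseline is a constant level plus a static per-pixel texture
#' drawn once per movie.
#'
#' @param cell_map a `cacti_cellmap`.
#' @param traces matrix `n_cells x n_frames` of noiseless per-cell amplitudes.
#' @param baseline constant baseline level (a.u., must be >= 0).
#' @param soma_gain,nucleus_gain pixel gains; `nucleus_gain < soma_gain`.
#' @param noise list with `mu` and `sigma2` (Gaussian noise parameters).
#' @param texture_sd standard deviation of the static baseline texture.
#' @param schedules optional list of `cacti_schedule` to attach as ground truth.
#' @param seed integer RNG seed (noise and texture).
#' @return `cacti_movie`: frames array `(n_frames, height, width)` plus the
#'   complete generative ground truth.
#' @export
render_movie <- function(cell_map, traces, baseline = 1.0, soma_gain = 1.0,
                         nucleus_gain = 0.6, noise = noise_params(),
                         texture_sd = 0.05, schedules = NULL, seed = NULL) {
  stopifnot(inherits(cell_map, "cacti_cellmap"))
  if (baseline < 0) stop_config("movie: baseline must be >= 0")
  if (soma_gain <= 0 || nucleus_gain <= 0) stop_config("movie: gains must be > 0")
  if (nucleus_gain >= soma_gain)
    stop_config("movie: nucleus_gain must be < soma_gain")
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  if (nrow(traces) != length(cell_map$contours))
    stop_config("movie: traces rows (%d) != number of cells (%d)",
                nrow(traces), length(cell_map$contours))
  h <- cell_map$field_shape[1]; w <- cell_map$field_shape[2]
  n_frames <- ncol(traces)
  with_seed(seed, {
    base_img <- matrix(baseline, h, w) +
      matrix(stats::rnorm(h * w, 0, texture_sd), h, w)
    base_img[base_img < 0] <- 0
    # per-cell gain images as sparse (linear index, gain) pairs
    gain_idx <- vector("list", nrow(traces))
    gain_val <- vector("list", nrow(traces))
    for (i in seq_along(cell_map$contours)) {
      ct <- cell_map$contours[[i]]
      soma_lin <- ct$soma_mask[, 2] + 1L + ct$soma_mask[, 1] * h
      nuc_lin <- ct$nucleus_mask[, 2] + 1L + ct$nucleus_mask[, 1] * h
      gain_idx[[i]] <- c(soma_lin, nuc_lin)
      gain_val[[i]] <- c(rep(soma_gain, length(soma_lin)),
                         rep(nucleus_gain, length(nuc_lin)))
    }
    frames <- array(0, dim = c(n_frames, h, w))
    frame_buf <- matrix(0, h, w)
    for (t in seq_len(n_frames)) {
      frame_buf[] <- base_img
      for (i in seq_len(nrow(traces))) {
        a <- traces[i, t]
        if (a > 0) frame_buf[gain_idx[[i]]] <-
            frame_buf[gain_idx[[i]]] + gain_val[[i]] * a
      }
      frames[t, , ] <- frame_buf
    }
    if (noise$sigma2 > 0)
      frames <- frames + array(stats::rnorm(length(frames), noise$mu,
                                            sqrt(noise$sigma2)), dim = dim(frames))
    else if (noise$mu != 0) frames <- frames + noise$mu
    structure(list(frames = frames, cell_map = cell_map,
                   schedules = schedules, noiseless_traces = traces,
                   baseline = baseline, baseline_image = base_img,
                   soma_gain = soma_gain, nucleus_gain = nucleus_gain,
                   noise = noise, seed = seed),
              class = "cacti_movie")
  })
}

#' Gaussian noise parameters
#' @param mu mean (default 0).
#' @param sigma2 variance (default 0.1).
#' @export
noise_params <- function(mu = 0, sigma2 = 0.1) {
  if (sigma2 < 0) stop_config("noise: sigma2 must be >= 0")
  list(mu = mu, sigma2 = sigma2)
}

#' Simulate a complete ground-truthed movie
#'
#' Convenience driver chaining contour generation, map assembly, activity
#' sampling, trace rendering and movie rendering, all under one seed.
#'
#' @param n_frames movie length in frames.
#' @param n_cells number of cells (default 16).
#' @param field_shape `(height, width)` of the field of view.
#' @param overlap_range per-cell overlap-degree bounds.
#' @param count_range,rise_range,tau_range,amp_meanlog,amp_sdlog passed to
#'   [sample_activity()].
#' @param baseline,soma_gain,nucleus_gain,noise,texture_sd passed to
#'   [render_movie()].
#' @param library_size size of the procedural contour library to draw from.
#' @param geometry a [geometry_config()].
#' @param seed master seed; all stages derive from it.
#' @return a `cacti_movie`.
#' @export
simulate_movie <- function(n_frames = 1000, n_cells = 16,
                           field_shape = c(100, 100), overlap_range = c(1, 4),
                           count_range = c(2, 16), rise_range = c(1, 8),
                           tau_range = c(10, 12), amp_meanlog = 0,
                           amp_sdlog = 0.3, baseline = 1.0, soma_gain = 1.0,
                           nucleus_gain = 0.6, noise = noise_params(),
                           texture_sd = 0.05, library_size = 64,
                           geometry = geometry_config(), seed = 1L) {
  lib <- generate_contour_library(library_size, geometry, seed = seed)
  cmap <- build_cell_map(lib, n_cells = n_cells, overlap_range = overlap_range,
                         field_shape = field_shape, seed = seed + 1L)
  schedules <- lapply(seq_len(n_cells), function(i)
    sample_activity(n_frames, cell_id = i, count_range = count_range,
                    rise_range = rise_range, tau_range = tau_range,
                    amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
                    seed = seed + 100L + i))
  traces <- do.call(rbind, lapply(schedules, render_trace))
  render_movie(cmap, traces, baseline = baseline, soma_gain = soma_gain,
               nucleus_gain = nucleus_gain, noise = noise,
               texture_sd = texture_sd, schedules = schedules,
               seed = seed + 2L)
}

#' Ground-truth activity labels of a simulated movie
#' @param movie a `cacti_movie` with schedules attached.
#' @return a `cacti_labels` object of (onset, peak) intervals per cell.
#' @export
movie_labels <- function(movie) {
  stopifnot(inherits(movie, "cacti_movie"))
  if (is.null(movie$schedules)) stop_config("movie has no attached schedules")
  ivs <- lapply(movie$schedules, function(s) {
    m <- cbind(onset = s$events$onset, peak = s$events$peak)
    merge_intervals(m)
  })
  new_labels(ivs,
             cell_ids = vapply(movie$schedules, `[[`, integer(1), "cell_id"),
             n_frames = dim(movie$frames)[1])
}

#' @export
print.cacti_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cacti_movie> %d frames, %dx%d px, %d cells, noise sigma2=%g\n",
              d[1], d[2], d[3], length(x$cell_map$contours), x$noise$sigma2))
  invisible(x)
}

#' Export a simulated movie and its ground truth to plain files
#'
#' Writes the frame stack as a 16-bit multi-page TIFF (with the affine
#' intensity scaling recorded in a metadata file), the contours and the
#' (cell_id, onset, peak) labels as columnar text.
#'
#' @param movie a `cacti_movie`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
export_ground_truth <- function(movie, out_dir) {
  stopifnot(inherits(movie, "cacti_movie"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(movie = file.path(out_dir, "movie.tif"),
                contours = file.path(out_dir, "contours.csv"),
                labels = file.path(out_dir, "labels.csv"),
                meta = file.path(out_dir, "movie.tif.meta.txt"))
  write_movie(movie$frames, paths$movie, meta_path = paths$meta,
              extra_meta = c(seed = movie$seed %||% NA,
                             baseline = movie$baseline,
                             soma_gain = movie$soma_gain,
                             nucleus_gain = movie$nucleus_gain,
                             noise_sigma2 = movie$noise$sigma2))
  write_contours(movie$cell_map, paths$contours)
  write_labels(movie_labels(movie), paths$labels)
  invisible(paths)
}
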