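#' Sample a per-cell transient schedule
#'
#' Event counts are uniform over an integer range stated per 1000 frames and
#' scaled proportionally to the movie length (2-16 events per 1000 frames is
#' 1.2-9.6 transients/min at 10 Hz). Rise lengths are uniform integers
#' (1-8 frames, 100-800 ms at 10 Hz), decay time constants uniform reals
#' (10-12 frames), and amplitudes log-normal (median `exp(amp_meanlog)` a.u.).
#' Onsets are drawn so that the peak lies inside the movie and no two onsets
#' coincide within a cell.
#'
#' @param n_frames movie length in frames (>= 100).
#' @param cell_id integer id attached to the schedule.
#' @param count_range integer(2), event-count bounds per 1000 frames.
#' @param rise_range integer(2), rise length bounds (frames).
#' @param tau_range numeric(2), decay time-constant bounds (frames).
#' @param amp_meanlog,amp_sdlog log-normal amplitude parameters.
#' @param seed integer RNG seed.
#' @return `cacti_schedule` with an `events` data frame
#'   (onset, rise_len, peak, decay_tau, amplitude) sorted by onset.
#' @export
sample_activity <- function(n_frames, cell_id = 1L, count_range = c(2, 16),
                            rise_range = c(1, 8), tau_range = c(10, 12),
                            amp_meanlog = 0, amp_sdlog = 0.3, seed = NULL) {
  if (n_frames < 100) stop_config("activity: n_frames must be >= 100")
  scale <- n_frames / 1000
  lo <- max(0L, as.integer(round(count_range[1] * scale)))
  hi <- as.integer(round(count_range[2] * scale))
  if (hi < lo) stop_config("activity: infeasible count_range")
  max_fit <- (n_frames - max(rise_range) - 1) %/% 2
  if (lo > max_fit)
    stop_config("activity: %d events cannot fit in %d frames", lo, n_frames)
  with_seed(seed, {
    k <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    rise <- if (k) sample(seq(rise_range[1], rise_range[2]), k, replace = TRUE) else integer(0)
    tau <- stats::runif(k, tau_range[1], tau_range[2])
    amp <- stats::rlnorm(k, amp_meanlog, amp_sdlog)
    onset <- integer(0)
    if (k) {
      avail <- 0:(n_frames - max(rise_range) - 2)
      if (length(avail) < k)
        stop_config("activity: %d events cannot fit in %d frames", k, n_frames)
      onset <- sort(sample(avail, k))
    }
    ev <- data.frame(onset = onset, rise_len = rise,
                     peak = onset + rise, decay_tau = tau, amplitude = amp)
    ev <- ev[order(ev$onset), , drop = FALSE]
    rownames(ev) <- NULL
    structure(list(cell_id = as.integer(cell_id), events = ev,
                   n_frames = as.integer(n_frames)),
              class = "cacti_schedule")
  })
}

#' Render the noiseless fluorescence trace of one schedule
#'
#' Each transient ramps linearly from 0 at its onset to its amplitude at the
#' peak, then decays as `a * exp(-t / tau)`. Transients that overlap within
#' one cell sum (modelling summation of calcium events).
#'
#' @param schedule a `cacti_schedule`.
#' @return numeric vector of length `n_frames` (>= 0).
#' @export
render_trace <- function(schedule) {
  stopifnot(inherits(schedule, "cacti_schedule"))
  n <- schedule$n_frames
  tr <- numeric(n)
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]; rl <- ev$rise_len[i]
    a <- ev$amplitude[i]; tau <- ev$decay_tau[i]
    ramp_t <- 0:rl
    idx <- on + ramp_t
    keep <- idx < n
    tr[idx[keep] + 1L] <- tr[idx[keep] + 1L] + a * ramp_t[keep] / rl
    pk <- on + rl
    dec_len <- min(n - 1L - pk, ceiling(12 * tau))
    if (dec_len >= 1) {
      t <- seq_len(dec_len)
      tr[pk + t + 1L] <- tr[pk + t + 1L] + a * exp(-t / tau)
    }
  }
  tr
}
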