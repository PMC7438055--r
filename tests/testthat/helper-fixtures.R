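# Shared small fixtures, built once per test run. Everything here is
# deterministic (fixed seeds) and desk-scale so the whole suite stays fast.

fixture_env <- new.env(parent = emptyenv())

# A short default-parameter movie shared by IO / trace / patch tests.
fixture_movie <- function() {
  if (is.null(fixture_env$movie))
    fixture_env$movie <- simulate_movie(n_frames = 300, seed = 11)
  fixture_env$movie
}

fixture_labels <- function() {
  if (is.null(fixture_env$labels))
    fixture_env$labels <- movie_labels(fixture_movie())
  fixture_env$labels
}

fixture_putative <- function() {
  if (is.null(fixture_env$putative))
    fixture_env$putative <- detect_putative_transients_movie(fixture_movie())
  fixture_env$putative
}

# Tiny model configuration for gradient / shape tests.
tiny_activity_config <- function(seq_len = 5, window = 9, n_streams = 2)
  activity_model_config(seq_len = seq_len, window = window,
                        n_streams = n_streams, conv_filters = c(2L, 3L, 4L),
                        att_units = 3L, recurrent_width = 2L,
                        merge_width = 4L, preset = "desk")

# Flatten a nested parameter list to (path, length) leaves for gradient
# checking; unnamed list elements are addressed by index.
flatten_params <- function(z, path = "") {
  if (is.list(z)) {
    out <- list()
    nms <- names(z)
    for (j in seq_along(z)) {
      acc <- if (!is.null(nms) && nzchar(nms[j])) paste0(path, "$", nms[j])
             else paste0(path, "[[", j, "]]")
      out <- c(out, flatten_params(z[[j]], acc))
    }
    out
  } else list(list(path = path, len = length(z)))
}

get_leaf <- function(z, path) eval(parse(text = paste0("z", path)))

set_leaf <- function(z, path, i, v) {
  eval(parse(text = paste0("z", path, "[", i, "] <- v")))
  z
}
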