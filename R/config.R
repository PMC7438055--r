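# Run configuration: one plain-text (YAML) file drives every stage; CLI
# flags override file values. All defaults are the package's canonical
# settings (100-frame sequences of 25x25 windows, stride 10, 80/20 split,
# 60/30/10 stratification, 0.5 activation threshold, 0.7/0.2 overlap
# correlations, 15% overlap fraction, 16-cell maps, sigma2 = 0.1 noise).

#' Default run configuration
#' @return nested named list of all tunables.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulator = list(
      n_frames = 1000L, n_cells = 16L, field_shape = c(100L, 100L),
      overlap_range = c(1L, 4L), count_range = c(2L, 16L),
      rise_range = c(1L, 8L), tau_range = c(10, 12),
      amp_meanlog = 0, amp_sdlog = 0.3, baseline = 1.0,
      soma_gain = 1.0, nucleus_gain = 0.6,
      noise_mu = 0, noise_sigma2 = 0.1, texture_sd = 0.05),
    pipeline = list(
      seq_len = 100L, window = 25L, stride = 10L,
      stratify_target = c(0.60, 0.30, 0.10), w_fake = 5,
      split_ratio = 0.8),
    model = list(
      preset = "desk", dropout_rate = 0.5, lr = 6e-3,
      epochs = 10L, batch_size = 4L),
    thresholds = list(
      activation = 0.5, r_high = 0.7, r_low = 0.2,
      overlap_min_fraction = 0.15))
}

#' Validate a run configuration
#'
#' Checks ranges and shapes; errors name the offending field.
#' @param config nested list as from [default_run_config()].
#' @return the config, invisibly, if valid.
#' @export
validate_run_config <- function(config) {
  need <- function(cond, field, msg)
    if (!isTRUE(cond)) stop_config("config: field '%s' %s", field, msg)
  s <- config$simulator
  need(s$n_frames >= 100, "simulator.n_frames", "must be >= 100")
  need(s$n_cells >= 1, "simulator.n_cells", "must be >= 1")
  need(s$noise_sigma2 >= 0, "simulator.noise_sigma2", "must be >= 0")
  need(s$nucleus_gain < s$soma_gain, "simulator.nucleus_gain",
       "must be < soma_gain")
  need(s$baseline >= 0, "simulator.baseline", "must be >= 0")
  p <- config$pipeline
  need(p$seq_len > 0 && p$window > 0 && p$stride > 0, "pipeline",
       "seq_len, window, stride must be positive")
  need(abs(sum(p$stratify_target) - 1) < 1e-8, "pipeline.stratify_target",
       "must sum to 1")
  need(p$split_ratio > 0 && p$split_ratio < 1, "pipeline.split_ratio",
       "must be in (0, 1)")
  m <- config$model
  need(m$dropout_rate >= 0 && m$dropout_rate < 1, "model.dropout_rate",
       "must be in [0, 1)")
  need(m$epochs >= 1, "model.epochs", "must be >= 1")
  t <- config$thresholds
  need(t$activation > 0 && t$activation < 1, "thresholds.activation",
       "must be in (0, 1)")
  need(t$r_high > t$r_low, "thresholds.r_high", "must exceed r_low")
  need(t$overlap_min_fraction > 0 && t$overlap_min_fraction <= 1,
       "thresholds.overlap_min_fraction", "must be in (0, 1]")
  invisible(config)
}

#' Read / write a run configuration file (YAML)
#' @param path file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config: file not found: %s", path)
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config nested configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest (seed, config hash, versions) next to outputs
#' @param config the run configuration used.
#' @param seed the seed used.
#' @param path manifest path.
#' @param extra named character vector of extra entries.
#' @export
write_manifest <- function(config, seed, path, extra = NULL) {
  cfg_file <- tempfile(fileext = ".yml")
  yaml::write_yaml(config, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  lines <- c(sprintf("seed\t%s", seed),
             sprintf("config_md5\t%s", hash),
             sprintf("package_version\t%s",
                     as.character(utils::packageVersion("cacti"))),
             sprintf("r_version\t%s", R.version.string),
             if (!is.null(extra)) sprintf("%s\t%s", names(extra), extra))
  writeLines(lines, path)
  invisible(path)
}
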