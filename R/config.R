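#' Read a flat YAML configuration file
#'
#' Optional configuration for the command-line interface. Recognized keys
#' mirror the function arguments: `walk.gamma`, `walk.gammas`, `walk.tol`,
#' `walk.max_iter`, `walk.norm`, `rvm.max_iter`, `rvm.width`,
#' `rvm.prune_threshold`, `rvm.conv_tol`, `score_scale`, `threshold`,
#' `cv.repeats`, `cv.folds`, `cv.refit_walk_per_fold`. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to a YAML file with flat `section.key` entries.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read config files.")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Config file must contain key: value pairs.")
  known <- c(
    "walk.gamma", "walk.gammas", "walk.tol", "walk.max_iter", "walk.norm",
    "walk.snapshot_iters",
    "rvm.max_iter", "rvm.width", "rvm.prune_threshold", "rvm.conv_tol",
    "score_scale", "threshold", "cv.repeats", "cv.folds",
    "cv.refit_walk_per_fold"
  )
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    abort(sprintf("Unknown config key(s): %s.", paste(bad, collapse = ", ")))
  }
  cfg
}
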