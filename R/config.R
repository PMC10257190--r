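# Run configuration: defaults, file loading, flag precedence, validation.
# Defaults follow the method's published operating point: exploration
# constant 0.5, success reward 10, top-50 expansion, 500-iteration budget,
# stopping thresholds eps1 = 0.015 and eps2 = 3, 20 training epochs with
# dropout 0.1.

.CONFIG_DEFAULTS <- list(
  c = 0.5, z = 10, k = 50L, iter_limit = 500L, max_depth = 15L,
  exploitation = "printed",
  eps1 = 0.015, eps2 = 3, epochs = 20L, dropout = 0.1, rounds_max = 20L,
  seed = 0L, verbosity = 1L
)

.validate_config <- function(cfg) {
  if (cfg$c <= 0) stop_egmcts("config", "c must be > 0")
  if (cfg$z <= 1) stop_egmcts("config", "z must exceed 1")
  if (cfg$k < 1) stop_egmcts("config", "k must be >= 1")
  if (cfg$iter_limit < 1) stop_egmcts("config", "iter_limit must be >= 1")
  if (cfg$max_depth < 1) stop_egmcts("config", "max_depth must be >= 1")
  if (!cfg$exploitation %in% c("printed", "plain")) {
    stop_egmcts("config", "exploitation must be 'printed' or 'plain'")
  }
  if (cfg$eps1 < 0 || cfg$eps2 < 0) stop_egmcts("config", "eps1/eps2 must be >= 0")
  if (cfg$epochs < 0) stop_egmcts("config", "epochs must be >= 0")
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    stop_egmcts("config", "dropout must lie in [0, 1)")
  }
  if (cfg$rounds_max < 1) stop_egmcts("config", "rounds_max must be >= 1")
  cfg
}

#' Build a run configuration
#'
#' Defaults, optionally overridden by a flat key-value file (YAML), then
#' by explicit overrides -- flags beat the file, the file beats the
#' defaults. Unknown keys and out-of-range values are configuration
#' errors.
#'
#' @param path Optional configuration file (flat YAML mapping).
#' @param overrides Named list of explicit overrides.
#' @return Validated list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .CONFIG_DEFAULTS
  apply_layer <- function(cfg, layer, origin) {
    for (key in names(layer)) {
      if (!key %in% names(.CONFIG_DEFAULTS)) {
        stop_egmcts("config", sprintf("unknown configuration key '%s' (%s)",
                                      key, origin))
      }
      value <- layer[[key]]
      if (is.integer(.CONFIG_DEFAULTS[[key]])) value <- as.integer(value)
      cfg[[key]] <- value
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop_egmcts("io", sprintf("no such file: %s", path))
    cfg <- apply_layer(cfg, yaml::read_yaml(path), origin = path)
  }
  cfg <- apply_layer(cfg, overrides, origin = "flags")
  structure(.validate_config(cfg), class = "run_config")
}

#' Write a run configuration to a flat YAML file
#'
#' Round-trips with [load_config()]: `load_config(dump_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Planner view of a run configuration
#'
#' @param cfg A `run_config`.
#' @param stop_on_proven Planner mode.
#' @return A `planner_config`.
#' @export
as_planner_config <- function(cfg, stop_on_proven = TRUE) {
  planner_config(c = cfg$c, z = cfg$z, k = cfg$k, iter_limit = cfg$iter_limit,
                 max_depth = cfg$max_depth, seed = cfg$seed,
                 exploitation = cfg$exploitation,
                 stop_on_proven = stop_on_proven)
}

#' Provenance block for result artifacts
#'
#' Effective configuration, seed and package version, echoed into every
#' output file written by the command-line interface.
#'
#' @param cfg A `run_config`.
#' @return Named list.
#' @export
config_provenance <- function(cfg) {
  list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("egmcts")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
}
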