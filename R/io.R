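#' Write / read a tidy time-series CSV
#'
#' Long format with columns `time`, `variable`, `value` (and any extra
#' columns passed through). The reader sorts rows by time within variable,
#' validates that each (time, variable) pair is unique, and returns values
#' at full precision.
#'
#' @param x for `write_timeseries()`: an `adm1_sim` (its timeseries is
#'   pivoted long) or a data frame already in long format.
#' @param path CSV file path.
#' @return `read_timeseries()` returns a tibble sorted by variable, time.
#' @export
write_timeseries <- function(x, path) {
  df <- if (inherits(x, "adm1_sim")) {
    tidyr::pivot_longer(x$timeseries, -"time", names_to = "variable",
                        values_to = "value")
  } else {
    stopifnot(all(c("time", "variable", "value") %in% names(x)))
    x
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "variable", "value") %in% names(df))) {
    abort("time-series file must have columns time, variable, value")
  }
  key <- paste(df$time, df$variable)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    abort(paste0("duplicate (time, variable) pairs at row(s): ",
                 paste(head(rows, 10), collapse = ", ")),
          class = "madm1_format_error")
  }
  df <- df[order(df$variable, df$time), ]
  tibble::as_tibble(df)
}

config_schema <- function() {
  list(
    variant = function(v) is.character(v) && v %in% c("ctrl", "NH3", "NH3_HCl"),
    params_file = function(v) is.character(v) && length(v) == 1,
    X_ac1_0 = function(v) is.numeric(v) && v >= 0,
    X_pro1_0 = function(v) is.numeric(v) && v >= 0,
    HRT = function(v) is.numeric(v) && v > 0,
    t_end = function(v) is.numeric(v) && v > 0,
    dt_out = function(v) is.numeric(v) && v > 0,
    rtol = function(v) is.numeric(v) && v > 0,
    atol = function(v) is.numeric(v) && v > 0,
    seed = function(v) is.numeric(v) && v == round(v),
    out = function(v) is.character(v),
    log_level = function(v) v %in% c("quiet", "info", "debug")
  )
}

#' Load and validate a run configuration
#'
#' A YAML mapping with any of the keys: `variant`, `params_file`, `X_ac1_0`,
#' `X_pro1_0`, `HRT`, `t_end`, `dt_out`, `rtol`, `atol`, `seed`, `out`,
#' `log_level`. Unknown keys, missing referenced files and out-of-range
#' values are rejected with an error naming the key. Defaults are filled for
#' anything omitted.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file values (flags
#'   override file values).
#' @return list of class `adm1_config` with all keys present.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(variant = "NH3", params_file = NA_character_,
                   X_ac1_0 = NA_real_, X_pro1_0 = NA_real_,
                   HRT = NA_real_, t_end = 79, dt_out = 0.1,
                   rtol = 1e-8, atol = 1e-12, seed = 1L,
                   out = NA_character_, log_level = "info")
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    yaml::read_yaml(path) %||% list()
  }
  raw <- modifyList(raw, overrides)
  schema <- config_schema()
  bad <- setdiff(names(raw), names(schema))
  if (length(bad)) abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  for (k in names(raw)) {
    v <- raw[[k]]
    if (!isTRUE(schema[[k]](v))) {
      abort(paste0("config key '", k, "' has an invalid value"))
    }
  }
  cfg <- modifyList(defaults, raw)
  if (!is.na(cfg$params_file) && !file.exists(cfg$params_file)) {
    abort(paste0("config key 'params_file': file does not exist: ", cfg$params_file))
  }
  structure(cfg, class = "adm1_config", source = path)
}

#' @rdname load_config
#' @param config an `adm1_config` list.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, function(v) is.na(v)[1], TRUE)]
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Machine-readable run manifest
#'
#' Enough provenance to reproduce a run: a hash of the resolved
#' configuration, the seed, and the package version.
#'
#' @param config an `adm1_config` list.
#' @return list with `config_hash`, `seed`, `package`, `version`, `created`.
#' @export
run_manifest <- function(config) {
  list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package = "madm1",
    version = as.character(utils::packageVersion("madm1")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Assemble simulation inputs from a configuration
#'
#' Resolves a validated configuration into the parameter set, schedule and
#' initial-condition overrides, and runs the simulation.
#'
#' @param config an `adm1_config` from [load_config()].
#' @return an `adm1_sim`; the manifest is attached as attribute `"manifest"`.
#' @export
run_from_config <- function(config) {
  params <- if (!is.na(config$params_file)) read_params(config$params_file)
            else adm1_params()
  for (k in c("X_ac1_0", "X_pro1_0", "HRT")) {
    if (!is.na(config[[k]])) params[[k]] <- config[[k]]
  }
  validate_params(params)
  schedule <- experiment_schedule(config$variant, params, t_end = config$t_end)
  sim <- simulate_reactor(schedule, params, dt_out = config$dt_out,
                          rtol = config$rtol, atol = config$atol)
  attr(sim, "manifest") <- run_manifest(config)
  if (!is.na(config$out)) write_timeseries(sim, config$out)
  sim
}
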