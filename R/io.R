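# Configuration, CSV interchange with commented metadata headers, grey-map
# export, and the run manifest.

#' Write a data.frame as CSV with a commented metadata header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param metadata named list written as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_csv_with_header <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, paste(format(metadata[[k]]), collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a per-gate intensity table from CSV
#'
#' Ingests tables with one row per (condition, replicate, voltage, gate)
#' holding a fluorescence intensity — the layout emitted by [run_scan()] and
#' the row-logical layout of published per-gate source-data files. Columns
#' may be renamed via `column_map`. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping required column names to
#'   names in the file, e.g. `c(voltage_V = "voltage")`.
#' @return validated intensity data.frame with columns `condition`,
#'   `replicate`, `voltage_V`, `gate_index`, `intensity`.
#' @export
read_intensity_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("no data: ", path))
  if (nrow(df) == 0L) stop("no data: ", path)
  req <- c("condition", "replicate", "voltage_V", "gate_index", "intensity")
  if (!is.null(column_map)) {
    for (want in names(column_map)) {
      have <- column_map[[want]]
      if (!have %in% names(df))
        stop("column_map names missing column '", have, "' in ", path)
      names(df)[names(df) == have] <- want
    }
  }
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  df <- df[, req]
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad) > 0)
    stop("negative or non-numeric intensity at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad_gate <- which(df$gate_index != round(df$gate_index) | df$gate_index < 1)
  if (length(bad_gate) > 0)
    stop("invalid gate index at data row(s): ",
         paste(utils::head(bad_gate, 5), collapse = ", "))
  key <- interaction(df$condition, df$replicate, df$voltage_V, df$gate_index,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (condition, replicate, voltage, gate) at data row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  df
}

#' Write an intensity table to CSV
#'
#' @param table intensity data.frame.
#' @param path output path.
#' @param metadata named list for the commented header (seeds, config hash).
#' @return `path`, invisibly.
#' @export
write_intensity_csv <- function(table, path, metadata = list()) {
  check_intensity_table(table)
  write_csv_with_header(
    table[, c("condition", "replicate", "voltage_V", "gate_index", "intensity")],
    path, metadata = metadata)
}

#' Write a plain (P2) portable grey map
#'
#' @param m integer-valued matrix of grey levels.
#' @param path output path.
#' @param maxval maximum grey value.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path, maxval = 255L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
               as.character(maxval)), con)
  write(t(pmin(pmax(round(m), 0L), maxval)), con, ncolumns = ncol(m))
  invisible(path)
}

#' Default run configuration
#'
#' The full study configuration as a nested list: geometry, solver, mixture
#' presets, scan protocol, normalization, statistics and seeds. Serializable
#' to/from YAML with [write_run_config()] / [read_run_config()].
#'
#' @param seed base seed; per-replicate seeds are derived from it.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    geometry = list(n_gates = 27L, first_width_um = 73, last_width_um = 25,
                    group_size = 3L, length_cm = 3.5, depth_um = 20,
                    background_width_um = 200, apex_angle_deg = 60),
    solver = list(spacing_um = 3, reference_voltage = 1000,
                  calibrate_to = list(voltage = 1800, ekmr = 2.3e10)),
    protocol = list(blocking_voltage = 2100, start_voltage = 1800,
                    end_voltage = 600, step = 300),
    populations = list(
      n = list(locations = c(3.5e9, 5.5e9, 1.2e10, 1.8e10),
               weights = c(0.30, 0.30, 0.25, 0.15),
               dispersions = 0.05, n_particles = 2000L, replicates = 3L),
      g = list(locations = c(4.0e9, 7.5e9, 1.1e10, 2.3e10),
               weights = c(0.25, 0.30, 0.30, 0.15),
               dispersions = 0.05, n_particles = 2000L, replicates = 4L)),
    noise_sd = 2,
    weight_jitter = 0.25,
    normalize = "max",
    stats = list(voltage = 1200, alpha = 0.05),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [default_run_config()]. Missing keys
#'   fall back to the defaults.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_lists(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  structure(merge_lists(cfg, user), class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  # stable digest without extra dependencies: hash the serialized YAML text
  txt <- yaml::as.yaml(unclass(config))
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997 + 1)) %% 1e9
}

#' Write a JSON run manifest
#'
#' Records package version, seed, config hash and output files of a run.
#'
#' @param config the `run_config` used.
#' @param outputs character vector of output paths.
#' @param path manifest path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, outputs, path) {
  manifest <- list(
    package = "dcidep",
    version = as.character(utils::packageVersion("dcidep")),
    seed = config$seed,
    config_hash = config_hash(config),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
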