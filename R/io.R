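known_config_keys <- function() {
  d <- default_config_raw()
  lapply(d, function(sec) if (is.list(sec)) names(sec) else NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with `model:`, `protocol:`, `population:`,
#' `noise:` and `analysis:` sections, fills unspecified values from the
#' packaged defaults, rejects unknown keys, and range-checks every value
#' (validation errors name the offending key). A `NULL` or missing path
#' returns the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for defaults.
#' @return An object of class `"run_config"`: list with components
#'   `model` ([fate_model()]), `protocol` ([pulse_protocol()]),
#'   `population` (list `dist`, `n`, `s_levels`), `noise`
#'   ([noise_model()]), `analysis` (list of analysis settings) and
#'   `version`.
#' @examples
#' cfg <- load_config()
#' cfg$model
#' @export
load_config <- function(path = NULL) {
  d <- default_config_raw()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path) %||% list()
  }
  known <- known_config_keys()
  bad_sec <- setdiff(names(user), names(d))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  merged <- d
  for (sec in names(user)) {
    if (!is.list(user[[sec]])) { merged[[sec]] <- user[[sec]]; next }
    bad <- setdiff(names(user[[sec]]), known[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    for (k in names(user[[sec]])) merged[[sec]][[k]] <- user[[sec]][[k]]
  }
  m <- merged$model
  model <- fate_model(alpha_N = m$alpha_N, alpha_G = m$alpha_G,
                      K_GN = m$K_GN, K_NG = m$K_NG, h_N = m$h_N,
                      h_G = m$h_G, gamma_N = m$gamma_N, gamma_G = m$gamma_G,
                      gamma_X = m$gamma_X, s = m$s, K_s = m$K_s, m = m$m,
                      mode = m$mode)
  pr <- merged$protocol
  protocol <- pulse_protocol(pr$t_start, pr$t_end, pr$t_final)
  po <- merged$population
  population <- list(
    dist = dose_distribution(po$dose_family, po$dose_location, po$dose_scale),
    n = check_number(po$n_cells, "n_cells", lower = 1),
    s_levels = unlist(po$s_levels))
  nz <- merged$noise
  noise <- noise_model(nz$sigma_mult, nz$background, nz$background_sd,
                       nz$label_flip)
  an <- merged$analysis
  check_number(an$frame_interval, "frame_interval", lower = 0,
               strict_lower = TRUE)
  check_number(an$n_boot, "n_boot", lower = 1)
  check_number(an$prominence_frac, "prominence_frac", lower = 0, upper = 1)
  check_number(an$cluster_k, "cluster_k", lower = 1)
  structure(list(model = model, protocol = protocol, population = population,
                 noise = noise, analysis = an,
                 version = merged$version %||% d$version),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration (version %s)\n", x$version))
  print(x$model); print(x$protocol)
  print(x$population$dist)
  cat(sprintf("  population: n = %d, s_levels = %s\n", x$population$n,
              paste(x$population$s_levels, collapse = ", ")))
  print(x$noise)
  invisible(x)
}

config_to_plain <- function(config) {
  list(
    model = unclass(config$model),
    protocol = unclass(config$protocol),
    population = list(
      dose_family = config$population$dist$family,
      dose_location = config$population$dist$location,
      dose_scale = config$population$dist$scale,
      n_cells = config$population$n,
      s_levels = as.list(config$population$s_levels)),
    noise = unclass(config$noise),
    analysis = config$analysis,
    version = config$version)
}

#' Write a run configuration to YAML
#'
#' Serializes a [load_config()] object so that saving and re-loading is
#' the identity.
#'
#' @param config A `"run_config"` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_config(load_config(), f)
#' @export
save_config <- function(config, path) {
  check_flag_class(config, "run_config")
  yaml::write_yaml(config_to_plain(config), path)
  invisible(path)
}

trace_cols <- c("cell_id", "time_h", "channel", "intensity")

#' Write a long-format trace table
#'
#' Tidy CSV with columns `cell_id`, `time_h`, `channel`, `intensity`;
#' numeric values are written with full (17 significant digit) precision
#' so a write/read round trip is lossless.
#'
#' @param table Data frame with the four trace columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @examples
#' tl <- generate_timelapse(n = 2, frame_interval = 10, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_traces(tl$noisy, f)
#' @export
write_traces <- function(table, path) {
  if (!all(trace_cols %in% names(table)))
    stop("trace table must have columns ",
         paste(trace_cols, collapse = ", "), call. = FALSE)
  out <- table[trace_cols]
  out$time_h <- sprintf("%.17g", out$time_h)
  out$intensity <- sprintf("%.17g", out$intensity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format trace table
#'
#' Reads and validates a CSV written by [write_traces()] (or any table
#' with the same columns): required columns present, no duplicate
#' `(cell_id, time_h, channel)` rows, times strictly increasing within
#' each cell and channel. Rows are returned in canonical order (cell,
#' channel, time). Cells missing frames present for other cells are
#' flagged in the `"gap_cells"` attribute.
#'
#' @param path CSV path.
#' @return Data frame with columns `cell_id`, `time_h`, `channel`,
#'   `intensity`.
#' @examples
#' tl <- generate_timelapse(n = 2, frame_interval = 10, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_traces(tl$noisy, f)
#' nrow(read_traces(f))
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trace_cols, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- paste(df$cell_id, df$time_h, df$channel, sep = "\r")
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (cell_id, time_h, channel) at row %d", row),
         call. = FALSE)
  }
  ord <- order(df$cell_id, df$channel, df$time_h)
  df <- df[ord, trace_cols]
  rownames(df) <- NULL
  by_cc <- split(seq_len(nrow(df)), paste(df$cell_id, df$channel))
  for (idx in by_cc) {
    tt <- df$time_h[idx]
    if (any(diff(tt) <= 0)) {
      bad <- idx[which(diff(tt) <= 0)[1L] + 1L]
      stop(sprintf("non-monotone times within a cell at row %d", bad),
           call. = FALSE)
    }
  }
  all_times <- sort(unique(df$time_h))
  gap_cells <- unique(unlist(lapply(split(df, df$cell_id), function(dc) {
    per_chan <- table(dc$channel)
    if (any(per_chan < length(all_times))) dc$cell_id[1L] else NULL
  })))
  structure(df, gap_cells = gap_cells)
}
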