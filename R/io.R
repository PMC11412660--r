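#' Output file family
#'
#' A finished run is written as a family of files sharing a stem
#' (`<series name>-<serial>`): a central YAML log pointing at everything
#' else, one NPY var file per recorded state variable with axis order
#' (t, x, y, z), an integer NPY mask, CSV sensor histories and
#' electrograms, and a YAML tip-data file. All writers are deterministic
#' byte-for-byte for fixed inputs (stable YAML key order, fixed CSV float
#' formatting).
#'
#' @name io_formats
NULL

#' Write variable frames as an NPY var file
#'
#' @param stem output stem (path prefix).
#' @param var_name state-variable name (file suffix `_<var>.txyz.npy`).
#' @param frames array with time as the first (slowest) axis and the
#'   spatial axes following in (x, y, z, ...) order; 2D runs must carry a
#'   z axis of extent 1 (shape `(T, Nx, Ny, 1)`).
#' @return the file path, invisibly.
#' @export
write_var_npy <- function(stem, var_name, frames) {
  d <- dim(frames)
  if (is.null(d) || length(d) < 4L)
    stop_validation("var frames must be (t, x, y, z[, ...]) shaped")
  path <- paste0(stem, "_", var_name, ".txyz.npy")
  write_npy(frames, path, dtype = "float32")
  invisible(path)
}

#' @rdname write_var_npy
#' @param path an NPY file written by [write_var_npy()].
#' @export
read_var_npy <- function(path) read_npy(path)

#' Write the inhom mask as an integer NPY file
#'
#' Stored once, for the initial time step, with shape `(1, Nx, Ny, Nz)`.
#' @param stem output stem.
#' @param inhom integer label array ([inhom_field()] or plain array).
#' @export
write_inhom_npy <- function(stem, inhom) {
  if (!is.integer(inhom) && any(inhom != round(inhom)))
    stop_validation("inhom labels must be integers")
  sh <- dim(inhom)
  if (is.null(sh)) sh <- length(inhom)
  sh4 <- c(sh, rep(1L, max(0, 3 - length(sh))))
  arr <- array(as.integer(inhom), dim = c(1L, sh4))
  path <- paste0(stem, "_inhom.txyz.npy")
  write_npy(arr, path, dtype = "int32")
  invisible(path)
}

#' @rdname write_inhom_npy
#' @param path an NPY file written by [write_inhom_npy()].
#' @export
read_inhom_npy <- function(path) read_npy(path)

#' Write / read the central YAML log
#'
#' The log is the central file of a result set: it echoes the simulation
#' setup and holds the manifest of the other output files (paths relative
#' to the log's directory). Reading preserves unknown keys.
#' @param stem output stem.
#' @param log a named list (see [build_sim_log()]).
#' @export
write_log_yaml <- function(stem, log) {
  path <- paste0(stem, "_log.yaml")
  yaml::write_yaml(log, path, precision = 15)
  invisible(path)
}

#' @rdname write_log_yaml
#' @param path a `_log.yaml` file.
#' @param check_manifest warn about manifest entries that do not resolve.
#' @export
read_log_yaml <- function(path, check_manifest = TRUE) {
  log <- yaml::read_yaml(path)
  if (check_manifest && !is.null(log$files)) {
    base <- dirname(path)
    for (f in unlist(log$files)) {
      if (!file.exists(file.path(base, f)))
        warning(sprintf("manifest entry '%s' not found next to the log", f),
                call. = FALSE)
    }
  }
  log
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x) & abs(x) < 1e15] <-
    sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}

write_rows_csv <- function(path, rows, header) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (!is.null(rows) && nrow(rows))
    writeLines(apply(rows, 1, function(r) paste(fmt_num(r), collapse = ",")),
               con)
  invisible(path)
}

#' Write / read sensor-history and electrogram CSV files
#'
#' Numeric values are written with full precision (round-trip exact through
#' the decimal representation); the header row carries the time column
#' followed by the recorded variable names (histories) or `phi_e`
#' (electrograms).
#' @param stem output stem.
#' @param id sensor/electrode index (file suffix `_hist<id>.csv` /
#'   `_egm<id>.csv`).
#' @param rows numeric matrix, first column time (ms), time-sorted.
#' @param var_names column names after time.
#' @export
write_history_csv <- function(stem, id, rows, var_names = NULL) {
  if (is.null(var_names))
    var_names <- colnames(rows)[-1]
  if (is.unsorted(rows[, 1]))
    stop_validation("history rows must be time-sorted")
  write_rows_csv(paste0(stem, "_hist", id, ".csv"), rows,
                 c("time", var_names))
}

#' @rdname write_history_csv
#' @export
write_egm_csv <- function(stem, id, rows) {
  if (is.unsorted(rows[, 1]))
    stop_validation("EGM rows must be time-sorted")
  write_rows_csv(paste0(stem, "_egm", id, ".csv"), rows, c("time", "phi_e"))
}

#' @rdname write_history_csv
#' @param path a CSV written by one of the writers.
#' @param check assert a monotone non-decreasing time column.
#' @export
read_history_csv <- function(path, check = TRUE) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d)
  if (check && nrow(m) > 1 && is.unsorted(m[, 1]))
    stop_validation("time column is not monotone")
  m
}

#' Write / read detected phase singularities as YAML
#'
#' Tips are grouped by frame time; within a frame, detection order is
#' preserved.
#' @param stem output stem.
#' @param tips_by_time list of per-frame data frames as produced by
#'   [detect_tips()] (may be empty), or a single data frame with a `time`
#'   column.
#' @param times frame times (required if `tips_by_time` is a list lacking
#'   times).
#' @export
write_tipdata_yaml <- function(stem, tips_by_time, times = NULL) {
  if (is.data.frame(tips_by_time)) {
    times <- unique(tips_by_time$time)
    tips_by_time <- lapply(times, function(tt)
      tips_by_time[tips_by_time$time == tt, , drop = FALSE])
  }
  if (is.null(times))
    times <- vapply(tips_by_time, function(d)
      if (nrow(d)) d$time[1] else NA_real_, 1)
  groups <- lapply(seq_along(tips_by_time), function(i) {
    d <- tips_by_time[[i]]
    list(time = times[i],
         tips = if (!nrow(d)) list() else lapply(seq_len(nrow(d)), function(r)
           list(position = as.numeric(d[r, c("x", "y", "z")]),
                plane = as.character(d$plane[r]),
                anchor = as.integer(d[r, c("i", "j", "k")]),
                isovalues = as.numeric(d[r, c("iso_f", "iso_g")]))))
  })
  path <- paste0(stem, "_tipdata.yaml")
  yaml::write_yaml(list(frames = groups), path, precision = 15)
  invisible(path)
}

#' @rdname write_tipdata_yaml
#' @param path a `_tipdata.yaml` file.
#' @return `read_tipdata_yaml()`: data frame with one row per tip
#'   (`time, x, y, z, plane, i, j, k, iso_f, iso_g`).
#' @export
read_tipdata_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  rows <- list()
  for (g in doc$frames) {
    for (tp in g$tips) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = g$time, x = tp$position[1], y = tp$position[2],
        z = tp$position[3], plane = tp$plane,
        i = tp$anchor[1], j = tp$anchor[2], k = tp$anchor[3],
        iso_f = tp$isovalues[1], iso_g = tp$isovalues[2])
    }
  }
  if (!length(rows))
    return(data.frame(time = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), plane = character(0), i = integer(0),
                      j = integer(0), k = integer(0), iso_f = numeric(0),
                      iso_g = numeric(0)))
  do.call(rbind, rows)
}

#' Assemble the log (metadata) of a finished run
#'
#' @param sim an `mw_sim`.
#' @return named list: schema version, stem, grid, model description
#'   (variables, projection, stepping tags, parameters), numerical settings
#'   (dt, CFL bound, duration), recorders, and an (initially empty) file
#'   manifest.
#' @export
build_sim_log <- function(sim) {
  cfg <- sim$config
  list(
    schema = "monowave-log-1",
    stem = cfg$stem,
    grid = list(shape = as.integer(sim$grid$shape),
                spacing = as.numeric(sim$grid$spacing),
                origin = as.numeric(sim$grid$origin)),
    model = list(name = sim$model$name,
                 variables = sim$model$var_names,
                 projection = as.numeric(sim$model$P),
                 steppings = sim$model$steppings,
                 parameters = sim$model$params),
    numerics = list(dt = sim$dt, cfl_bound = sim$cfl,
                    duration = cfg$duration, n_steps = sim$n_steps,
                    frame_interval = cfg$frame_interval,
                    n_parts = cfg$n_parts),
    seed = cfg$seed,
    frame_times = as.numeric(sim$frame_times),
    sensors = lapply(sim$sensors, function(s)
      list(vertex = s$vtx, vars = as.integer(s$vars), lag = s$lag)),
    electrodes = lapply(sim$electrodes, function(e)
      list(position = as.numeric(e$pos), prefactor = e$prefactor)),
    files = list()
  )
}

#' Write all outputs of a run
#'
#' Writes the var NPY files, the inhom mask, histories, electrograms, tip
#' data and finally the log with the complete manifest. The stem is
#' `<series name>-<serial>`; the serial defaults to a timestamp and should
#' be fixed for reproducible file sets.
#' @param sim an `mw_sim`.
#' @param outdir output directory (created if missing).
#' @param serial overrides the config's serial number.
#' @return named list of written file paths (the manifest plus the log).
#' @export
write_outputs <- function(sim, outdir, serial = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  if (is.null(serial)) serial <- cfg$serial
  if (is.null(serial)) serial <- format(Sys.time(), "%Y%m%dT%H%M%S")
  stem <- file.path(outdir, paste0(cfg$stem, "-", serial))
  manifest <- character(0)
  for (v in sim$frame_vars) {
    nm <- sim$model$var_names[v]
    p <- write_var_npy(stem, nm, frames_array(sim, v))
    manifest <- c(manifest, basename(p))
  }
  p <- write_inhom_npy(stem, sim$geometry$inhom)
  manifest <- c(manifest, basename(p))
  for (i in seq_along(sim$histories)) {
    p <- write_history_csv(stem, i - 1L, sim$histories[[i]])
    manifest <- c(manifest, basename(p))
  }
  for (i in seq_along(sim$egms)) {
    p <- write_egm_csv(stem, i - 1L, sim$egms[[i]])
    manifest <- c(manifest, basename(p))
  }
  if (!is.null(sim$tipdata)) {
    p <- write_tipdata_yaml(stem, sim$tipdata, times = sim$frame_times)
    manifest <- c(manifest, basename(p))
  }
  log <- sim$log
  log$files <- as.list(manifest)
  logp <- write_log_yaml(stem, log)
  c(stats::setNames(as.list(file.path(dirname(stem), manifest)), manifest),
    list(log = logp))
}
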