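#' Deterministic scenario fixtures
#'
#' Ready-made simulation setups reproducing the standard study conditions
#' at desk scale: a planar wave crossing a small square medium, S1S2
#' spiral induction, a two-model medium with obstacles, and the cuboid
#' conduction benchmark. Each scenario carries a complete YAML-ready
#' config (usable from [run_from_config()] and the command line), builds
#' fresh components on every run, and ships a list of qualitative
#' assertions that double as tests.
#'
#' @name scenarios
NULL

new_scenario <- function(name, config, assertions = list(), extras = list()) {
  structure(c(list(name = name, config = config, assertions = assertions),
              extras), class = "mw_scenario")
}

#' @export
print.mw_scenario <- function(x, ...) {
  cat(sprintf("<mw_scenario> %s: %s grid, model %s, duration %g ms\n",
              x$name, paste(x$config$grid$shape, collapse = "x"),
              if (!is.null(x$config$model$name)) x$config$model$name
              else "multi", x$config$sim$duration))
  invisible(x)
}

#' Run a scenario
#'
#' @param sc an `mw_scenario`.
#' @param n_parts,duration,dt,tips optional overrides.
#' @return the `mw_sim` result.
#' @export
run_scenario <- function(sc, n_parts = NULL, duration = NULL, dt = NULL,
                         tips = NULL) {
  parts <- parse_sim_config(sc$config)
  cfg <- parts$config
  if (!is.null(n_parts)) cfg$n_parts <- as.integer(n_parts)
  if (!is.null(duration)) cfg$duration <- duration
  if (!is.null(dt)) cfg$dt <- dt
  if (!is.null(tips)) cfg$tips <- tips
  run_simulation(parts$model, parts$geometry, parts$source, cfg,
                 sensors = parts$sensors, electrodes = parts$electrodes)
}

#' @rdname run_scenario
#' @param result an `mw_sim` from [run_scenario()].
#' @return `check_scenario()`: named logical vector of assertion outcomes.
#' @export
check_scenario <- function(sc, result) {
  vapply(sc$assertions, function(f) isTRUE(f(result)), TRUE)
}

#' Write a scenario's config as a YAML file
#'
#' @param sc an `mw_scenario`.
#' @param path output file.
#' @export
write_scenario_config <- function(sc, path) {
  yaml::write_yaml(sc$config, path, precision = 15)
  invisible(path)
}

# LAT column index for results whose model carries a LAT wrapper
lat_layer <- function(result) {
  col <- result$model$lat_col
  if (is.null(col)) stop_validation("scenario model has no LAT wrapper")
  array(result$state[, col], dim = result$grid$shape)
}

#' Planar wave crossing a small square medium
#'
#' Smooth-Karma tissue on a 30 x 30 grid (1 mm spacing, isotropic
#' diffusion); a set-stimulus on the strip x in \[0, 5\] mm at t = 0 sends
#' a planar wave in the +x direction. A LAT wrapper records the arrival
#' times, which must increase monotonically with x along the midline; no
#' phase singularities ever appear.
#'
#' @param duration simulated time, ms.
#' @export
scenario_planar_wave <- function(duration = 40) {
  cfg <- list(
    grid = list(shape = c(30L, 30L), spacing = c(1, 1)),
    diffusion = list(type = "iso", D = 1.0),
    model = list(name = "SmooKa",
                 wrappers = list(list(type = "lat", var = 1L,
                                      threshold = 1.0))),
    stimuli = list(list(vars = 1L, values = 1.0, mode = "set", t_on = 0,
                        shape = list(type = "cuboid", corner1 = c(0, 0),
                                     corner2 = c(5, 0)))),
    sensors = list(list(pos = c(15, 15), lag = 1.0)),
    sim = list(duration = duration, dt = 0.1, frame_interval = 10,
               stem = "planar", tips = "auto")
  )
  new_scenario(
    "planar_wave", cfg,
    assertions = list(
      lat_monotone_along_midline = function(res) {
        lat <- lat_layer(res)[, 15]
        lat <- lat[6:30]           # beyond the stimulated strip
        act <- lat >= 0
        all(act) && all(diff(lat) > 0)
      },
      no_tips_any_frame = function(res)
        all(vapply(res$tipdata, nrow, 1L) == 0L)
    )
  )
}

#' S1S2 spiral induction (cross-field stimulation)
#'
#' Aliev-Panfilov tissue (isotropic, D = 1.6 mm^2/ms, dx = 1 mm,
#' dt = 0.1 ms): a planar S1 wave starts at t = 0 from the left edge; when
#' its waveback clears the central sensor (voltage dropping below 10% of
#' the excited amplitude), the S2 stimulus depolarizes the bottom
#' half-plane, leaving a free wave end that curls into a rotor. The scaled
#' 60 x 60 variant keeps the full protocol at a quarter of the area.
#'
#' @param scaled use the 60 x 60 fast variant (default) instead of the
#'   full 120 x 120 medium.
#' @export
scenario_s1s2_spiral <- function(scaled = TRUE) {
  nx <- if (scaled) 60L else 120L
  mid <- (nx - 1) / 2
  cfg <- list(
    grid = list(shape = c(nx, nx), spacing = c(1, 1)),
    diffusion = list(type = "iso", D = 1.6),
    model = list(name = "AP"),
    stimuli = list(list(vars = 1L, values = 1.0, mode = "set", t_on = 0,
                        shape = list(type = "cuboid", corner1 = c(0, 0),
                                     corner2 = c(5, 0)))),
    triggers = list(list(pos = c(mid, mid), var = 1L, threshold = 0.1,
                         direction = "down",
                         activate = list(vars = 1L, values = 1.0,
                                         mode = "set", t_on = 0,
                                         shape = list(type = "halfplane",
                                                      origin = c(0, mid),
                                                      normal = c(0, 1))))),
    sensors = list(list(pos = c(mid, mid), lag = 1.0)),
    sim = list(duration = if (scaled) 300 else 838.6, dt = 0.1,
               frame_interval = 5, stem = "s1s2", tips = "auto")
  )
  new_scenario(
    "s1s2_spiral", cfg,
    assertions = list(
      s2_fired = function(res) length(res$trigger_log) == 1L,
      tip_within_100ms_of_s2 = function(res) {
        t2 <- res$trigger_log[[1]]$t
        counts <- vapply(res$tipdata, nrow, 1L)
        any(counts > 0 & res$frame_times > t2 &
              res$frame_times <= t2 + 100)
      },
      no_tips_before_s2 = function(res) {
        t2 <- res$trigger_log[[1]]$t
        all(vapply(res$tipdata, nrow, 1L)[res$frame_times < t2] == 0L)
      }
    ),
    extras = list(s2_time_hint = 426)
  )
}

#' Two-model medium with unexcitable obstacles
#'
#' Smooth-Karma tissue in two parameterizations (a slower-recovery region
#' on the right), with a disk and a rectangle of exterior (label 0)
#' obstacle, 0.2 mm spacing. A planar wave at t = 0 wraps around the
#' obstacles; a second, half-plane stimulus at t = 600 ms probes the
#' recovered medium. The scaled variant shrinks the sheet and stops after
#' the second stimulus.
#'
#' @param scaled use the reduced 50 x 35 sheet (default).
#' @export
scenario_inhom_multimodel <- function(scaled = TRUE) {
  sh <- if (scaled) c(50L, 35L) else c(100L, 70L)
  dx <- 0.2
  ext <- (sh - 1) * dx
  disk_c <- c(0.3 * ext[1], 0.5 * ext[2])
  rect1 <- c(0.6 * ext[1], 0.15 * ext[2])
  rect2 <- c(0.75 * ext[1], 0.35 * ext[2])
  labels <- matrix(1L, sh[1], sh[2])
  xs <- (seq_len(sh[1]) - 1) * dx
  ys <- (seq_len(sh[2]) - 1) * dx
  labels[xs > ext[1] / 2, ] <- 2L
  px <- matrix(xs, sh[1], sh[2])
  py <- matrix(ys, sh[1], sh[2], byrow = TRUE)
  labels[(px - disk_c[1])^2 + (py - disk_c[2])^2 <= (0.1 * ext[2])^2] <- 0L
  labels[px >= rect1[1] & px <= rect2[1] &
           py >= rect1[2] & py <= rect2[2]] <- 0L
  stim2_t <- 600
  cfg <- list(
    grid = list(shape = sh, spacing = c(dx, dx)),
    inhom = list(labels = as.integer(labels)),
    diffusion = list(type = "iso", D = 0.031),
    model = list(multi = list(list(name = "SmooKa"),
                              list(name = "SmooKa",
                                   params = list(tau_v = 150))),
                 wrappers = list(list(type = "lat", var = 1L,
                                      threshold = 1.0))),
    stimuli = c(list(list(vars = 1L, values = 2.0, mode = "set", t_on = 0,
                          shape = list(type = "cuboid",
                                       corner1 = c(0, 0),
                                       corner2 = c(2 * dx, 0)))),
                list(list(vars = 1L, values = 2.0, mode = "set",
                          t_on = stim2_t,
                          shape = list(type = "halfplane",
                                       origin = c(0, ext[2] / 2),
                                       normal = c(0, 1)))),
                if (!scaled)
                  list(list(vars = 1L, values = 2.0, mode = "set",
                            t_on = 921,
                            shape = list(type = "cuboid",
                                         corner1 = c(0, 0),
                                         corner2 = c(2 * dx, 0))))),
    sensors = list(list(pos = c(0.12 * ext[1], ext[2] / 2), lag = 1.0)),
    sim = list(duration = if (scaled) 660 else 2000.1, dt = 0.1,
               frame_interval = 20, stem = "inhom", tips = "auto")
  )
  new_scenario(
    "inhom_multimodel", cfg,
    assertions = list(
      exterior_diffusion_zero = function(res) {
        y <- apply_diffusion(res$geometry$stencil, res$state[, 1])
        all(y[!res$geometry$interior] == 0)
      },
      wave_wraps_obstacles = function(res) {
        lat <- res$state[, res$model$lat_col]
        all(lat[res$geometry$interior] >= 0)
      },
      no_tips_before_second_stimulus = function(res)
        all(vapply(res$tipdata, nrow, 1L)[res$frame_times < stim2_t] == 0L)
    ),
    extras = list(stim2_t = stim2_t)
  )
}

#' Cuboid conduction benchmark
#'
#' An excitation wave crosses a 20 x 7 x 3 mm cuboid with fibers along the
#' long axis (orthotropic diffusion, fiber diffusivity 0.12 mm^2/ms,
#' transverse 0.03), stimulated in a 1.5 mm corner cube at P1 = (0, 0, 0);
#' the local activation time at the far corner P8 = (20, 7, 3) mm
#' summarizes the conduction velocity. The Bueno-Orovio (EPI) model is
#' used. Refining dx from 0.5 to 0.2 mm speeds up transversal conduction
#' (coarse grids slow it down); time steps above the CFL bound make the
#' run abort with a stability error.
#'
#' @param dx grid spacing, mm (0.5, 0.2 or 0.1).
#' @param dt time step, ms.
#' @param duration simulated time, ms.
#' @export
scenario_benchmark_cuboid <- function(dx = 0.5, dt = 0.05, duration = 60) {
  sh <- as.integer(round(c(20, 7, 3) / dx)) + 1L
  cfg <- list(
    grid = list(shape = sh, spacing = rep(dx, 3)),
    diffusion = list(type = "aniso", Df = 0.12, Ds = 0.03, Dx = 0.03,
                     fibers = list(ef = c(1, 0, 0), es = c(0, 1, 0))),
    model = list(name = "BO",
                 wrappers = list(list(type = "lat", var = 1L,
                                      threshold = 0.5))),
    stimuli = list(list(vars = 1L, values = 1.0, mode = "set", t_on = 0,
                        shape = list(type = "cuboid",
                                     corner1 = c(0, 0, 0),
                                     corner2 = c(1.5, 1.5, 1.5)))),
    sim = list(duration = duration, dt = dt, frame_interval = duration,
               stem = "cuboid", record_vars = 1L)
  )
  new_scenario(
    "benchmark_cuboid", cfg,
    assertions = list(
      p8_activates_after_p1 = function(res) {
        lat <- lat_layer(res)
        p1 <- lat[1, 1, 1]; p8 <- lat[dim(lat)[1], dim(lat)[2], dim(lat)[3]]
        p1 >= 0 && p8 > p1
      }
    ),
    extras = list(
      lat_at_p8 = function(res) {
        lat <- lat_layer(res)
        lat[dim(lat)[1], dim(lat)[2], dim(lat)[3]]
      },
      lat_at = function(res, pos_mm) {
        lat <- lat_layer(res)
        idx <- round(pos_mm / res$grid$spacing) + 1
        lat[idx[1], idx[2], idx[3]]
      }
    )
  )
}
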