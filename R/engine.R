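#' Simulation configuration
#'
#' @param duration total simulated time, ms.
#' @param dt time step, ms, or `"auto"` to take `safety * cfl_bound`
#'   truncated to 3 significant digits. An explicit dt above the CFL bound
#'   is honored with a warning.
#' @param frame_interval interval between stored frames, ms (the initial
#'   condition always counts as a frame); default: one final frame.
#' @param sensorlag default sensor sampling interval, ms.
#' @param stem output stem: descriptive series name; the serial number
#'   defaults to a timestamp and can be fixed via `serial` for reproducible
#'   outputs.
#' @param serial serial-number string appended to the stem (default
#'   ISO-8601 timestamp).
#' @param seed RNG seed set at the start of the run.
#' @param n_parts number of x-slab domain partitions (default 1; partition
#'   count never changes the computed frames).
#' @param safety CFL safety factor for auto dt (default 0.9).
#' @param record_vars indices of state variables stored in frames (default
#'   all).
#' @param tips `NULL`, or a list with `vars` (pair of variable indices) and
#'   `iso` (their isovalues) enabling phase-singularity detection at every
#'   frame time; defaults are taken from the model when `tips = "auto"`.
#' @param outdir directory to write output files to (`NULL`: keep results
#'   in memory only).
#' @export
sim_config <- function(duration, dt = "auto", frame_interval = NULL,
                       sensorlag = 1, stem = "sim", serial = NULL,
                       seed = NULL, n_parts = 1L, safety = 0.9,
                       record_vars = NULL, tips = NULL, outdir = NULL) {
  if (duration <= 0) stop_validation("duration must be > 0")
  if (!identical(dt, "auto") && (!is.numeric(dt) || dt <= 0))
    stop_validation("dt must be > 0 or 'auto'")
  if (is.null(frame_interval)) frame_interval <- duration
  structure(list(duration = duration, dt = dt,
                 frame_interval = frame_interval, sensorlag = sensorlag,
                 stem = stem, serial = serial, seed = seed,
                 n_parts = as.integer(n_parts), safety = safety,
                 record_vars = record_vars, tips = tips, outdir = outdir),
            class = "sim_config")
}

#' Sensor specification
#'
#' Records the temporal evolution of selected state variables at one
#' (interior) vertex, sampled at the first time step at or after each
#' multiple of the lag.
#' @param pos sensor position, mm (snapped to the nearest vertex).
#' @param vars recorded variable indices (default all).
#' @param lag sampling interval, ms (default: the config's `sensorlag`).
#' @export
sensor_spec <- function(pos, vars = NULL, lag = NULL) {
  structure(list(pos = pos, vars = vars, lag = lag), class = "mw_sensor")
}

#' Tissue geometry: grid + diffusion + mask, with assembled stencil
#'
#' @param grid a [grid_spec()].
#' @param D scalar diffusivity (isotropic), mm^2/ms.
#' @param inhom optional [inhom_field()].
#' @return an `mw_geometry` holding the grid, mask, diffusion description
#'   and the assembled `stencil_op`.
#' @export
geometry_iso <- function(grid, D, inhom = NULL) {
  inhom <- as_inhom(grid, inhom)
  st <- isotropic_stencil(grid, D, 1, inhom)
  structure(list(grid = grid, inhom = inhom, interior = st$interior,
                 stencil = st, diffusion = diffusion_iso(D)),
            class = "mw_geometry")
}

#' @rdname geometry_iso
#' @param Df,Ds,Dx diffusivities along the fiber frame, mm^2/ms.
#' @param fibers a [fiber_field()].
#' @export
geometry_aniso <- function(grid, Df, Ds, Dx = Ds, fibers, inhom = NULL) {
  inhom <- as_inhom(grid, inhom)
  spec <- diffusion_aniso(Df, Ds, Dx, fibers)
  tensor <- build_diffusion_tensor(fibers, spec)
  st <- orthotropic_stencil(grid, tensor, 1, inhom)
  structure(list(grid = grid, inhom = inhom, interior = st$interior,
                 stencil = st, diffusion = spec, tensor = tensor),
            class = "mw_geometry")
}

#' @rdname geometry_iso
#' @param tensor a `tensor_field`.
#' @export
geometry_tensor <- function(grid, tensor, inhom = NULL) {
  inhom <- as_inhom(grid, inhom)
  st <- orthotropic_stencil(grid, tensor, 1, inhom)
  structure(list(grid = grid, inhom = inhom, interior = st$interior,
                 stencil = st, diffusion = tensor, tensor = tensor),
            class = "mw_geometry")
}

#' Split the grid into x-slab partitions
#'
#' Contiguous slabs along the x-axis whose column counts differ by at most
#' one; exterior vertices count toward the balance (they are still stored).
#' Each partition owns all vertices whose x-index falls in its range and
#' exchanges one ghost column with each neighbor (the stencil radius).
#'
#' @param grid a [grid_spec()].
#' @param inhom an [inhom_field()] (kept for the splitting contract;
#'   balancing is by stored vertices).
#' @param n_parts number of partitions (1 <= n_parts <= x extent).
#' @return list of partitions with `x_range` (1-based, inclusive) and
#'   `rows` (owned linear vertex indices).
#' @export
partition_domain <- function(grid, inhom = NULL, n_parts = 1L) {
  nx <- grid$shape[1]
  n_parts <- as.integer(n_parts)
  if (n_parts < 1L || n_parts > nx)
    stop_validation("n_parts must be between 1 and the grid's x extent")
  base <- nx %/% n_parts
  rem <- nx %% n_parts
  sizes <- rep(base, n_parts) + c(rep(1L, rem), rep(0L, n_parts - rem))
  hi <- cumsum(sizes)
  lo <- hi - sizes + 1L
  ix <- grid_indices(grid)[, 1]
  lapply(seq_len(n_parts), function(p) {
    structure(list(x_range = c(lo[p], hi[p]),
                   rows = which(ix >= lo[p] & ix <= hi[p]),
                   ghost = 1L),
              class = "mw_partition")
  })
}

#' Stability check
#'
#' Reports whether a state is finite and whether the time step respects the
#' CFL bound.
#' @param state numeric state (any shape).
#' @param dt time step, ms.
#' @param bound CFL bound, ms.
#' @return list with `ok`, `finite`, `within_bound`, `message`.
#' @export
check_stability <- function(state, dt, bound) {
  finite <- all(is.finite(state))
  within <- dt <= bound
  msg <- if (!finite)
    sprintf("non-finite state values (dt = %g ms, CFL bound %g ms)", dt, bound)
  else if (!within)
    sprintf("dt = %g ms exceeds the CFL bound %g ms", dt, bound)
  else "stable"
  list(ok = finite, finite = finite, within_bound = within, message = msg)
}

stop_stability <- function(step, t, dt, bound) {
  stop(structure(class = c("mw_stability_error", "error", "condition"),
                 list(message = sprintf(
                   paste0("numerical instability: non-finite state at step %d",
                          " (t = %g ms); dt = %g ms, CFL bound = %g ms"),
                   step, t, dt, bound),
                   call = NULL, step = step, t = t, dt = dt, bound = bound)))
}

# truncate to at most `digits` significant digits (round toward zero)
trunc_signif <- function(x, digits = 3) {
  if (!is.finite(x) || x == 0) return(x)
  f <- 10^(floor(log10(abs(x))) - digits + 1)
  trunc(x / f) * f
}

#' Add a stimulus to a running simulation
#'
#' Intended for trigger actions and scheduled events; the stimulus becomes
#' active according to its own window from the moment it is added.
#' @param sim the running simulation environment.
#' @param stim a [stimulus()].
#' @export
sim_add_stimulus <- function(sim, stim) {
  k <- length(sim$stimuli) + 1L
  sim$stimuli[[k]] <- stim
  sim$stim_chi[[k]] <- stimulus_chi(stim, sim$grid, sim$interior)
  sim$stim_applied[k] <- FALSE
  invisible(sim)
}

#' Replace the geometry of a running simulation
#'
#' Swaps the diffusion operator mid-run (e.g. from a scheduled event that
#' changes the diffusivity); subsequent steps use the new stencil.
#' @param sim the running simulation environment.
#' @param geometry an `mw_geometry` on the same grid.
#' @export
sim_set_geometry <- function(sim, geometry) {
  if (!identical(geometry$grid$shape, sim$grid$shape))
    stop_validation("replacement geometry must live on the same grid")
  sim$geometry <- geometry
  sim$Wparts <- lapply(sim$partitions, function(p)
    geometry$stencil$W[p$rows, , drop = FALSE])
  invisible(sim)
}

#' Run a simulation
#'
#' Initializes all interior vertices to the model's resting state and loops:
#' evaluate the right-hand side (projected diffusion + reaction + additive
#' stimuli) on every partition, advance by the per-variable scheme, apply
#' set-mode stimuli, run recording-wrapper updates, evaluate triggers and
#' scheduled events, check stability, then sample sensors/electrograms and
#' store frames when due. Aborts with a stability error naming the step and
#' the CFL bound if the state turns non-finite.
#'
#' @param model a `cell_model` (possibly wrapped / multi-model).
#' @param geometry an `mw_geometry`.
#' @param source an `mw_source` (stimuli, triggers, scheduled events).
#' @param config a [sim_config()].
#' @param sensors list of [sensor_spec()]s.
#' @param electrodes list of [electrode()]s (require a recorded-diffusion
#'   wrapper on the model).
#' @return an object of class `mw_sim`: frames (`$frames`, `$frame_times`,
#'   see [frames_array()]), sensor histories, electrograms, tip data, the
#'   final state, and the run log.
#' @export
run_simulation <- function(model, geometry, source = source_spec(),
                           config = sim_config(1), sensors = list(),
                           electrodes = list()) {
  grid <- geometry$grid
  n <- grid$n
  M <- model$M
  interior <- geometry$interior
  if (!any(interior))
    stop_validation("a runnable simulation needs at least one interior vertex")
  labels <- as.vector(geometry$inhom)
  if (isTRUE(model$is_multi) && max(labels) > length(model$submodels))
    stop_validation("inhom label exceeds the number of submodels")
  if (!is.null(config$seed)) set.seed(config$seed)

  maxP <- max(model$P)
  bound <- stencil_cfl(geometry$stencil, max(maxP, 0))
  dt <- config$dt
  if (identical(dt, "auto")) {
    dt <- if (is.finite(bound)) trunc_signif(config$safety * bound, 3) else 1
  } else if (is.finite(bound) && dt > bound) {
    warning(sprintf("dt = %g ms exceeds the CFL bound %g ms; expect instability",
                    dt, bound), call. = FALSE)
  }
  n_steps <- as.integer(ceiling(config$duration / dt - 1e-9))
  tol <- 1e-9 * max(dt, 1)

  sim <- new.env(parent = emptyenv())
  sim$grid <- grid; sim$interior <- interior; sim$geometry <- geometry
  sim$model <- model; sim$dt <- dt; sim$cfl <- bound
  sim$partitions <- partition_domain(grid, geometry$inhom, config$n_parts)
  sim$Wparts <- lapply(sim$partitions, function(p)
    geometry$stencil$W[p$rows, , drop = FALSE])
  sim$stimuli <- list(); sim$stim_chi <- list(); sim$stim_applied <- logical(0)
  for (s in source$stimuli) sim_add_stimulus(sim, s)
  sim$trigger_log <- list()

  ri <- which(interior)
  ctx_rhs <- list(labels = labels[ri])
  diffused <- which(model$P != 0)

  apply_op <- function(v) {
    y <- numeric(n)
    for (p in seq_along(sim$partitions)) {
      rows <- sim$partitions[[p]]$rows
      y[rows] <- as.numeric(sim$Wparts[[p]] %*% v)
    }
    y
  }
  ctx_post <- list(labels = labels, diffusion_of = apply_op)

  rhs <- function(U, t) {
    dU <- matrix(0, n, M)
    for (m in diffused) dU[, m] <- model$P[m] * apply_op(U[, m])
    dU[ri, ] <- dU[ri, ] +
      model$reaction_fn(U[ri, , drop = FALSE], t, ctx_rhs)
    for (k in seq_along(sim$stimuli)) {
      st <- sim$stimuli[[k]]
      if (st$mode == "add" && stimulus_active(st, t, tol)) {
        a <- st$amplitude(t)
        for (j in seq_along(st$vars))
          dU[, st$vars[j]] <- dU[, st$vars[j]] +
            sim$stim_chi[[k]] * (st$values[j] * a)
      }
    }
    dU
  }

  apply_set_stimuli <- function(U, t) {
    for (k in seq_along(sim$stimuli)) {
      st <- sim$stimuli[[k]]
      if (st$mode != "set") next
      instant <- st$t_off <= st$t_on + tol
      if (instant) {
        if (!sim$stim_applied[k] && t >= st$t_on - tol) {
          U <- apply_stimulus(st, U, grid, st$t_on, interior,
                              chi = sim$stim_chi[[k]])
          sim$stim_applied[k] <- TRUE
        }
      } else if (stimulus_active(st, t, tol)) {
        U <- apply_stimulus(st, U, grid, t, interior,
                            chi = sim$stim_chi[[k]])
      }
    }
    U
  }

  # trigger bookkeeping: edge detection per trigger (per partition for
  # "each" mode)
  trig_state <- lapply(source$triggers, function(tr)
    list(prev = rep(FALSE, length(sim$partitions)), fired = 0L))
  for (tr in source$triggers) {
    vtx <- attr(tr$condition, "vertex")
    if (!is.null(vtx) && !interior[vtx])
      stop_validation("trigger condition references an exterior vertex")
  }
  eval_triggers <- function(U, t) {
    for (i in seq_along(source$triggers)) {
      tr <- source$triggers[[i]]
      stt <- trig_state[[i]]
      if (tr$one_shot && stt$fired > 0L) next
      per <- vapply(seq_along(sim$partitions), function(p)
        isTRUE(tr$condition(U, t, sim$partitions[[p]]$rows)), TRUE)
      fire <- switch(tr$mode,
        any = any(per) && !any(stt$prev),
        all = all(per) && !all(stt$prev),
        specific = per[tr$partition] && !stt$prev[tr$partition],
        each = any(per & !stt$prev))
      stt$prev <- per
      if (isTRUE(fire)) {
        stt$fired <- stt$fired + 1L
        sim$trigger_log[[length(sim$trigger_log) + 1L]] <-
          list(trigger = i, t = t)
        tr$action(sim, t)
      }
      trig_state[[i]] <<- stt
    }
  }

  events_done <- rep(FALSE, length(source$events))
  run_events <- function(t) {
    for (i in seq_along(source$events)) {
      ev <- source$events[[i]]
      if (!events_done[i] && t >= ev$t_exec - tol) {
        events_done[i] <<- TRUE
        ev$action(sim, t)
      }
    }
  }

  # sensors
  sens <- lapply(sensors, function(s) {
    vtx <- grid_nearest_vertex(grid, s$pos)
    if (!interior[vtx]) stop_validation("sensor vertex must be interior")
    vars <- if (is.null(s$vars)) seq_len(M) else as.integer(s$vars)
    list(vtx = vtx, vars = vars,
         lag = if (is.null(s$lag)) config$sensorlag else s$lag,
         next_due = 0, rows = list())
  })
  # electrodes: need a recorded-diffusion variable
  egms <- lapply(electrodes, function(e) {
    rec <- model$recorded_diffusion
    if (is.null(rec))
      stop(paste("pseudo-EGM computation requires a recorded diffusion term:",
                 "wrap the model with wrap_record_diffusion()"))
    kern <- egm_kernel(grid, geometry$inhom, e)
    list(electrode = e, kernel = kern, col = rec[[1]],
         lag = e$lag, next_due = 0, rows = list())
  })

  frames <- list(); frame_times <- numeric(0)
  rec_vars <- if (is.null(config$record_vars)) seq_len(M)
              else as.integer(config$record_vars)
  tips_spec <- config$tips
  if (identical(tips_spec, "auto"))
    tips_spec <- list(vars = model$tip_vars, iso = model$tip_iso)
  tipdata <- list()

  sample_outputs <- function(U, t, frame_due) {
    for (i in seq_along(sens)) {
      s <- sens[[i]]
      if (t + tol >= s$next_due) {
        s$rows[[length(s$rows) + 1L]] <- c(t, U[s$vtx, s$vars])
        s$next_due <- t + s$lag
        sens[[i]] <<- s
      }
    }
    for (i in seq_along(egms)) {
      e <- egms[[i]]
      due <- is.null(e$lag) || t + tol >= e$next_due
      if (due) {
        phi <- sum(e$kernel * U[, e$col])
        e$rows[[length(e$rows) + 1L]] <- c(t, phi)
        if (!is.null(e$lag)) e$next_due <- t + e$lag
        egms[[i]] <<- e
      }
    }
    if (frame_due) {
      frames[[length(frames) + 1L]] <<- U[, rec_vars, drop = FALSE]
      frame_times[length(frame_times) + 1L] <<- t
      if (!is.null(tips_spec)) {
        tp <- detect_tips(U, grid, vars = tips_spec$vars,
                          iso = tips_spec$iso, inhom = geometry$inhom,
                          t = t, warn_range = FALSE)
        tipdata[[length(tipdata) + 1L]] <<- tp
      }
    }
  }

  # --- initialization (t = 0 counts as a frame) -----------------------
  U <- resting_matrix(model, labels)
  U0 <- U
  U <- apply_set_stimuli(U, 0)
  if (!is.null(model$post_step))
    U <- model$post_step(U, U0, 0, 0, ctx_post)
  eval_triggers(U, 0)
  run_events(0)
  sample_outputs(U, 0, frame_due = TRUE)
  next_frame <- config$frame_interval

  # --- main loop ------------------------------------------------------
  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * dt
    t1 <- step * dt
    Uold <- U
    U <- advance(model$steppings, rhs, U, t0, dt)
    U <- apply_set_stimuli(U, t1)
    if (!is.null(model$post_step))
      U <- model$post_step(U, Uold, t0, dt, ctx_post)
    eval_triggers(U, t1)
    run_events(t1)
    # divergence guard: non-finite values, or magnitudes far beyond any
    # physical state (unstable modes double per step and would take
    # hundreds of further steps to reach IEEE overflow)
    if (!all(is.finite(U)) || max(abs(U)) > 1e100)
      stop_stability(step, t1, dt, bound)
    frame_due <- t1 + tol >= next_frame
    sample_outputs(U, t1, frame_due)
    if (frame_due) next_frame <- t1 + config$frame_interval
  }

  histories <- lapply(seq_along(sens), function(i) {
    h <- do.call(rbind, sens[[i]]$rows)
    colnames(h) <- c("time", model$var_names[sens[[i]]$vars])
    h
  })
  egm_out <- lapply(seq_along(egms), function(i) {
    h <- do.call(rbind, egms[[i]]$rows)
    colnames(h) <- c("time", "phi_e")
    h
  })

  res <- structure(list(
    grid = grid, model = model, geometry = geometry,
    dt = dt, cfl = bound, n_steps = n_steps, duration = config$duration,
    frames = frames, frame_times = frame_times, frame_vars = rec_vars,
    state = U, histories = histories,
    sensors = lapply(sens, function(s) list(vtx = s$vtx, vars = s$vars,
                                            lag = s$lag)),
    egms = egm_out, electrodes = electrodes,
    tipdata = if (is.null(tips_spec)) NULL else tipdata,
    tips_spec = tips_spec,
    trigger_log = sim$trigger_log,
    config = config), class = "mw_sim")
  res$log <- build_sim_log(res)
  if (!is.null(config$outdir)) res$files <- write_outputs(res, config$outdir)
  res
}

#' Extract a variable's frames as a (t, x, y, z) array
#'
#' 2D simulations get a z axis of extent 1, matching the output-file
#' contract; 1D simulations get y and z axes of extent 1.
#' @param sim an `mw_sim`.
#' @param var state-variable index (must be among the recorded variables).
#' @export
frames_array <- function(sim, var = 1L) {
  k <- match(var, sim$frame_vars)
  if (is.na(k)) stop_validation("variable was not recorded in frames")
  sh <- sim$grid$shape
  sh4 <- c(sh, rep(1L, max(0, 3 - length(sh))))
  Tn <- length(sim$frames)
  arr <- array(0, dim = c(Tn, sh4))
  for (i in seq_len(Tn))
    arr[i, , , ] <- array(sim$frames[[i]][, k], dim = sh4)
  arr
}

#' @export
print.mw_sim <- function(x, ...) {
  cat(sprintf("<mw_sim> %s on %s grid: %d steps, dt = %g ms (CFL %g ms), %d frames\n",
              x$model$name, paste(x$grid$shape, collapse = "x"),
              x$n_steps, x$dt, signif(x$cfl, 4), length(x$frames)))
  if (length(x$trigger_log))
    cat(sprintf("  triggers fired at: %s ms\n",
                paste(signif(vapply(x$trigger_log, `[[`, 1, "t"), 5),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.mw_sim <- function(object, ...) {
  u <- object$state[, 1]
  cat(sprintf("Simulation of %s, t in [0, %g] ms\n", object$model$name,
              object$n_steps * object$dt))
  cat(sprintf("  final u: range [%g, %g]\n", min(u), max(u)))
  cat(sprintf("  frames: %d at dt_frame = %g ms; sensors: %d; EGMs: %d\n",
              length(object$frames),
              object$config$frame_interval, length(object$histories),
              length(object$egms)))
  if (!is.null(object$tipdata))
    cat(sprintf("  tips per frame: %s\n",
                paste(vapply(object$tipdata, nrow, 1L), collapse = " ")))
  invisible(object)
}

#' Plot a state-variable frame
#'
#' Image plot of one stored frame of a 2D simulation.
#' @param x an `mw_sim`.
#' @param frame frame index (default: last).
#' @param var variable index.
#' @param ... passed to [graphics::image()].
#' @export
plot.mw_sim <- function(x, frame = length(x$frames), var = 1L, ...) {
  k <- match(var, x$frame_vars)
  if (is.na(k)) stop_validation("variable was not recorded in frames")
  sh <- x$grid$shape
  z <- matrix(x$frames[[frame]][, k], sh[1], prod(sh[-1]))[, seq_len(sh[2])]
  xs <- x$grid$origin[1] + (seq_len(sh[1]) - 1) * x$grid$spacing[1]
  ys <- x$grid$origin[2] + (seq_len(sh[2]) - 1) * x$grid$spacing[2]
  graphics::image(xs, ys, z, xlab = "x [mm]", ylab = "y [mm]",
                  main = sprintf("%s, t = %g ms", x$model$var_names[var],
                                 x$frame_times[frame]), ...)
  invisible(x)
}
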