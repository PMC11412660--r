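#' YAML simulation configuration
#'
#' A complete simulation can be described declaratively in YAML: grid,
#' diffusion (with optional fiber frame), inhom mask (inline or from an NPY
#' file), model choice with parameter overrides and wrapper stack, stimuli
#' with shapes, threshold triggers, sensors, electrodes, and the numerical
#' settings. [read_sim_config()] parses a file into ready-to-run
#' components; [run_from_config()] parses and runs in one call. Scenario
#' fixtures emit this format, so their configs double as worked examples.
#'
#' @name yaml_config
NULL

cfg_shape <- function(s, grid) {
  switch(s$type,
    cuboid = shape_cuboid(as.numeric(s$corner1), as.numeric(s$corner2)),
    sphere = shape_sphere(s$radius, as.numeric(s$center)),
    ellipsoid = shape_ellipsoid(as.numeric(s$radii), as.numeric(s$center),
                                if (is.null(s$angles)) c(0, 0, 0)
                                else as.numeric(s$angles)),
    ellipse_xy = shape_ellipse_xy(as.numeric(s$radii), as.numeric(s$center)),
    cylinder_z = shape_cylinder_z(s$radius, as.numeric(s$center)),
    halfplane = shape_halfplane(as.numeric(s$origin), as.numeric(s$normal)),
    npy = shape_from_array(grid, read_npy(s$path)),
    all = shape_all(),
    stop_validation(sprintf("unknown shape type '%s'", s$type)))
}

cfg_stimulus <- function(s, grid) {
  stimulus(vars = as.integer(s$vars),
           values = as.numeric(s$values),
           mode = if (is.null(s$mode)) "set" else s$mode,
           shape = if (is.null(s$shape)) shape_all()
                   else cfg_shape(s$shape, grid),
           t_on = if (is.null(s$t_on)) 0 else s$t_on,
           t_off = if (is.null(s$t_off)) {
             if (is.null(s$t_on)) 0 else s$t_on
           } else s$t_off)
}

cfg_model <- function(m) {
  model <- if (!is.null(m$multi)) {
    subs <- lapply(m$multi, function(sm)
      do.call(make_model, c(list(name = sm$name),
                            if (is.null(sm$params)) list() else sm$params)))
    multi_model(subs)
  } else {
    params <- if (is.null(m$params)) list() else m$params
    do.call(make_model, c(list(name = m$name), params))
  }
  if (!is.null(m$steppings)) model$steppings <- as.character(m$steppings)
  for (w in m$wrappers) {
    model <- switch(w$type,
      record_diffusion = wrap_record_diffusion(model, as.integer(w$which)),
      record_reaction = wrap_record_reaction(model, as.integer(w$which)),
      lat = wrap_record_lat(model, as.integer(w$var), w$threshold),
      ldt = wrap_record_ldt(model, as.integer(w$var), w$threshold),
      rescale = rescale_model(model,
        time_factor = if (is.null(w$time_factor)) 1 else w$time_factor,
        space_factor = if (is.null(w$space_factor)) 1 else w$space_factor,
        var_scale = w$var_scale, var_shift = w$var_shift),
      stop_validation(sprintf("unknown wrapper type '%s'", w$type)))
  }
  model
}

#' @rdname yaml_config
#' @param path path to a YAML config file (relative NPY paths resolve
#'   against the config's directory).
#' @return `read_sim_config()`: list with `model`, `geometry`, `source`,
#'   `config`, `sensors`, `electrodes`, ready for [run_simulation()].
#' @export
read_sim_config <- function(path) {
  parse_sim_config(yaml::read_yaml(path), dirname(path))
}

#' @rdname yaml_config
#' @param doc a config as a nested list (the parsed YAML document).
#' @param base directory against which relative NPY paths resolve.
#' @export
parse_sim_config <- function(doc, base = ".") {
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  grid <- grid_spec(as.integer(doc$grid$shape),
                    as.numeric(doc$grid$spacing),
                    if (is.null(doc$grid$origin)) 0
                    else as.numeric(doc$grid$origin))
  inhom <- if (is.null(doc$inhom)) NULL
  else if (!is.null(doc$inhom$npy)) {
    arr <- read_npy(resolve(doc$inhom$npy))
    d <- dim(arr)
    # stored masks carry a leading time axis of extent 1
    if (!is.null(d) && length(d) > grid$N && d[1] == 1L)
      arr <- array(arr, dim = d[-1])
    if (length(dim(arr)) > grid$N)
      arr <- array(arr, dim = dim(arr)[seq_len(grid$N)])
    inhom_field(grid, arr)
  } else inhom_field(grid, array(as.integer(unlist(doc$inhom$labels)),
                                 dim = grid$shape))
  dif <- doc$diffusion
  model <- cfg_model(doc$model)
  geometry <- if (identical(dif$type, "iso")) {
    geometry_iso(grid, dif$D, inhom)
  } else {
    fibers <- if (!is.null(dif$fibers$ef_npy)) {
      fiber_field(read_npy(resolve(dif$fibers$ef_npy)),
                  read_npy(resolve(dif$fibers$es_npy)))
    } else {
      fiber_field(as.numeric(dif$fibers$ef), as.numeric(dif$fibers$es))
    }
    geometry_aniso(grid, dif$Df, dif$Ds,
                   if (is.null(dif$Dx)) dif$Ds else dif$Dx, fibers, inhom)
  }
  stimuli <- lapply(doc$stimuli, cfg_stimulus, grid = grid)
  triggers <- lapply(doc$triggers, function(tr) {
    cond <- condition_threshold(grid, as.numeric(tr$pos),
                                as.integer(tr$var), tr$threshold,
                                if (is.null(tr$direction)) "down"
                                else tr$direction)
    s2 <- cfg_stimulus(tr$activate, grid)
    act <- function(sim, t) {
      s2t <- s2
      s2t$t_on <- t + s2$t_on
      s2t$t_off <- t + s2$t_off
      sim_add_stimulus(sim, s2t)
    }
    trigger(cond, act, one_shot = TRUE)
  })
  sensors <- lapply(doc$sensors, function(s)
    sensor_spec(as.numeric(s$pos), vars = s$vars, lag = s$lag))
  electrodes <- lapply(doc$electrodes, function(e)
    electrode(as.numeric(e$pos),
              prefactor = if (is.null(e$prefactor)) 1 else e$prefactor,
              lag = e$lag))
  sc <- doc$sim
  tips <- sc$tips
  if (isTRUE(tips) || identical(tips, "auto")) tips <- "auto"
  config <- sim_config(
    duration = sc$duration,
    dt = if (is.null(sc$dt)) "auto" else sc$dt,
    frame_interval = sc$frame_interval,
    sensorlag = if (is.null(sc$sensorlag)) 1 else sc$sensorlag,
    stem = if (is.null(sc$stem)) "sim" else sc$stem,
    serial = sc$serial, seed = sc$seed,
    n_parts = if (is.null(sc$n_parts)) 1L else sc$n_parts,
    record_vars = sc$record_vars, tips = tips, outdir = sc$outdir)
  list(model = model, geometry = geometry,
       source = source_spec(stimuli = stimuli, triggers = triggers),
       config = config, sensors = sensors, electrodes = electrodes)
}

#' @rdname yaml_config
#' @param stem,seed,n_parts,duration,outdir optional overrides of the
#'   file's settings.
#' @return `run_from_config()`: the `mw_sim` result.
#' @export
run_from_config <- function(path, stem = NULL, seed = NULL, n_parts = NULL,
                            duration = NULL, outdir = NULL) {
  parts <- read_sim_config(path)
  cfg <- parts$config
  if (!is.null(stem)) cfg$stem <- stem
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(n_parts)) cfg$n_parts <- as.integer(n_parts)
  if (!is.null(duration)) cfg$duration <- duration
  if (!is.null(outdir)) cfg$outdir <- outdir
  run_simulation(parts$model, parts$geometry, parts$source, cfg,
                 sensors = parts$sensors, electrodes = parts$electrodes)
}
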