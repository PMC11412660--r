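test_that("shape indicators follow the documented conventions", {
  s <- shape_sphere(1, c(0, 0, 0))
  expect_equal(shape_indicator(s, c(0, 0, 0)), 1)
  expect_equal(shape_indicator(s, c(2, 0, 0)), 0)

  r <- shape_cuboid(c(0, 0, 0), c(5, 0, 0))
  expect_equal(shape_indicator(r, c(10, 0, 0)), 0)
  expect_equal(shape_indicator(r, c(3, 7, -2)), 1)  # degenerate axes free
  expect_equal(shape_indicator(r, c(5, 0, 0)), 1)   # inclusive corner

  h <- shape_halfplane(c(0, 0, 0), c(1, 0, 0))
  expect_equal(shape_indicator(h, c(-1, 0, 0)), 1)
  expect_equal(shape_indicator(h, c(1, 0, 0)), 0)
  expect_equal(shape_indicator(h, c(0, 5, 5)), 1)   # boundary is inside

  # pure and idempotent
  x <- c(0.3, -0.2, 0.1)
  expect_identical(shape_indicator(s, x), shape_indicator(s, x))

  e <- shape_ellipsoid(c(2, 1, 1), c(0, 0, 0), angles = c(pi / 2, 0, 0))
  expect_equal(shape_indicator(e, c(0, 1.9, 0)), 1)  # long axis now along y
  expect_equal(shape_indicator(e, c(1.9, 0, 0)), 0)
})

test_that("array-backed shapes evaluate the nearest vertex", {
  g <- grid_spec(c(4, 4), 1)
  vals <- matrix(0, 4, 4); vals[2, 3] <- 0.5
  s <- shape_from_array(g, vals)
  expect_equal(shape_indicator(s, c(1, 2)), 0.5)
  expect_equal(shape_indicator(s, c(1.2, 2.2)), 0.5)  # snaps
  expect_equal(shape_indicator(s, c(0, 0)), 0)
  expect_error(shape_from_array(g, matrix(2, 4, 4)),
               class = "mw_validation_error")
})

test_that("set-mode stimulation blends with the indicator", {
  g <- grid_spec(c(30, 30), 1)
  U <- matrix(0, g$n, 2)
  st <- stimulus(1L, 1, "set", shape_cuboid(c(0, 0), c(5, 0)), t_on = 0)
  U2 <- apply_stimulus(st, U, g, 0)
  pos <- grid_positions(g)
  inside <- pos[, 1] <= 5
  expect_equal(U2[inside, 1], rep(1, sum(inside)))
  expect_equal(U2[!inside, 1], rep(0, sum(!inside)))
  expect_equal(U2[, 2], rep(0, g$n))

  # chi == 0 leaves the state untouched
  none <- stimulus(1L, 1, "set", shape_cuboid(c(100, 100), c(101, 101)))
  expect_identical(apply_stimulus(none, U, g, 0), U)

  # chi == 1 makes the variable uniform regardless of prior state
  all_st <- stimulus(1L, 0.7, "set", shape_all(), t_on = 0)
  U3 <- matrix(runif(g$n * 2), g$n, 2)
  U4 <- apply_stimulus(all_st, U3, g, 0)
  expect_equal(U4[, 1], rep(0.7, g$n))
})

test_that("add-mode deposits value x window quadrature", {
  # inert variable: du/dt = q inside the window, so u gains q*w
  m <- model_1varpoly(k = 0)
  g <- grid_spec(c(3, 1), 1)
  q <- 0.35; w <- 2
  src <- source_spec(stimuli = list(
    stimulus(1L, q, "add", shape_all(), t_on = 1, t_off = 1 + w)))
  res <- run_simulation(m, geometry_iso(g, 0), src,
                        sim_config(5, dt = 0.1))
  expect_equal(res$state[1, 1], q * w, tolerance = q * 0.15)
})

test_that("triggers fire on the false-to-true transition, once if one-shot", {
  g <- grid_spec(c(5, 1), 1)
  fired <- 0L
  tr <- trigger(function(state, t, rows) TRUE,
                function(sim, t) fired <<- fired + 1L, one_shot = TRUE)
  res <- run_simulation(model_1varpoly(k = 0), geometry_iso(g, 0),
                        source_spec(triggers = list(tr)),
                        sim_config(2, dt = 0.1))
  expect_identical(fired, 1L)   # already true at t = 0: first evaluation

  never <- 0L
  tr2 <- trigger(function(state, t, rows) FALSE,
                 function(sim, t) never <<- never + 1L)
  run_simulation(model_1varpoly(k = 0), geometry_iso(g, 0),
                 source_spec(triggers = list(tr2)), sim_config(2, dt = 0.1))
  expect_identical(never, 0L)

  # repeating (non one-shot) trigger refires on each transition
  flips <- 0L
  tr3 <- trigger(function(state, t, rows) (round(t * 10) %% 4) < 2,
                 function(sim, t) flips <<- flips + 1L, one_shot = FALSE)
  run_simulation(model_1varpoly(k = 0), geometry_iso(g, 0),
                 source_spec(triggers = list(tr3)), sim_config(2, dt = 0.1))
  expect_gt(flips, 1L)
})

test_that("a waveback passage fires the downward-crossing condition at the right time", {
  # traveling pulse scripted as set-stimuli at the sensor vertex: rise at
  # t = 2, fall at t = 6; the trigger must fire at the fall, not at rest
  g <- grid_spec(c(5, 1), 1)
  cond <- condition_threshold(g, c(2, 0), 1, 0.5, "down")
  src <- source_spec(
    stimuli = list(stimulus(1L, 1, "set", shape_all(), t_on = 2),
                   stimulus(1L, 0, "set", shape_all(), t_on = 6)),
    triggers = list(trigger(cond, function(sim, t) NULL)))
  res <- run_simulation(model_1varpoly(k = 0), geometry_iso(g, 0), src,
                        sim_config(10, dt = 0.1))
  expect_length(res$trigger_log, 1L)
  expect_equal(res$trigger_log[[1]]$t, 6, tolerance = 0.11)
})

test_that("scheduled events run once at the first step reaching t_exec", {
  g <- grid_spec(c(4, 1), 1)
  log <- numeric(0)
  evs <- list(schedule_event(0.6, function(sim, t) log <<- c(log, 1)),
              schedule_event(0.6, function(sim, t) log <<- c(log, 2)),
              schedule_event(0.25, function(sim, t) log <<- c(log, 3)))
  run_simulation(model_1varpoly(k = 0), geometry_iso(g, 0),
                 source_spec(events = evs), sim_config(1, dt = 0.1))
  # same-time events in registration order; each exactly once
  expect_identical(log, c(3, 1, 2))
})

test_that("an event swapping the diffusivity changes subsequent conduction", {
  m <- wrap_record_lat(model_ap(), 1L, 0.5)
  g <- grid_spec(c(40L, 3L), 1)
  make_src <- function(with_event) source_spec(
    stimuli = list(stimulus(1L, 1, "set", shape_cuboid(c(0, 0), c(2, 0)))),
    events = if (with_event) list(schedule_event(6, function(sim, t)
      sim_set_geometry(sim, geometry_iso(sim$grid, 0.25)))) else list())
  base <- run_simulation(m, geometry_iso(g, 1), make_src(FALSE),
                         sim_config(30, dt = 0.1))
  slowed <- run_simulation(m, geometry_iso(g, 1), make_src(TRUE),
                           sim_config(30, dt = 0.1))
  lat_b <- matrix(base$state[, 3], 40, 3)[, 2]
  lat_s <- matrix(slowed$state[, 3], 40, 3)[, 2]
  # identical before the swap, slower (later LAT) well after it
  expect_equal(lat_b[lat_b >= 0 & lat_b < 5], lat_s[lat_s >= 0 & lat_s < 5])
  far <- 20
  expect_gt(lat_s[far], lat_b[far] * 1.3)
})

test_that("the S1S2 composition induces a rotor only when triggered", {
  sc <- scenario_s1s2_spiral()
  # control: trigger disabled -> plain S1 wave, no tips in a short window
  cfg <- sc$config
  cfg$triggers <- NULL
  parts <- parse_sim_config(cfg)
  parts$config$duration <- 120
  res <- run_simulation(parts$model, parts$geometry, parts$source,
                        parts$config, sensors = parts$sensors)
  expect_equal(sum(vapply(res$tipdata, nrow, 1L)), 0L)
})

test_that("s1s2_protocol wires the stimuli and trigger together", {
  g <- grid_spec(c(40L, 40L), 1)
  s1 <- stimulus(1L, 1, "set", shape_cuboid(c(0, 0), c(4, 0)), t_on = 0)
  s2 <- stimulus(1L, 1, "set", shape_halfplane(c(0, 19.5), c(0, 1)))
  proto <- s1s2_protocol(s1, s2, g, sensor_pos = c(20, 20), var = 1L,
                         threshold = 0.1)
  res <- run_simulation(model_ap(), geometry_iso(g, 1.6), proto,
                        sim_config(120, dt = 0.1, frame_interval = 5,
                                   tips = "auto"))
  expect_length(res$trigger_log, 1L)
  t2 <- res$trigger_log[[1]]$t
  counts <- vapply(res$tipdata, nrow, 1L)
  expect_true(any(counts > 0 & res$frame_times > t2 &
                    res$frame_times <= t2 + 100))
})
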