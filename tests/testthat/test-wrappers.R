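run_cable <- function(model, duration = 5, nx = 30L, D = 1, dt = 0.1,
                      stim_val = 1, frame_interval = 1, ...) {
  g <- grid_spec(c(nx, 3L), 1)
  geom <- geometry_iso(g, D)
  src <- source_spec(stimuli = list(
    stimulus(1L, stim_val, "set", shape_cuboid(c(0, 0), c(3, 0)), t_on = 0)))
  run_simulation(model, geom, src,
                 sim_config(duration, dt = dt,
                            frame_interval = frame_interval, ...))
}

test_that("recorded diffusion equals apply_diffusion of the same frame", {
  m <- wrap_record_diffusion(model_ap(), 1L)
  res <- run_cable(m, duration = 4)
  col <- m$recorded_diffusion[["1"]]
  for (fi in seq_along(res$frames)) {
    u <- res$frames[[fi]][, 1]
    rec <- res$frames[[fi]][, col]
    expect_equal(rec, apply_diffusion(res$geometry$stencil, u),
                 tolerance = 1e-14)
  }
  # far ahead of the front the medium is uniform: recorded term is 0 there
  last <- res$frames[[length(res$frames)]]
  far <- which(grid_positions(res$grid)[, 1] > 25)
  expect_equal(max(abs(last[far, col])), 0)
})

test_that("wrapping twice adds two independent recording variables", {
  m <- wrap_record_diffusion(wrap_record_diffusion(model_ap(), 1L), 1L)
  expect_equal(m$M, 4L)
  expect_equal(m$P[3:4], c(0, 0))
  res <- run_cable(m, duration = 2)
  expect_equal(res$state[, 3], res$state[, 4])   # same recorded quantity
})

test_that("recording wrappers leave the inner dynamics bit-identical", {
  base <- run_cable(model_ap(), duration = 4)
  wrapped <- run_cable(wrap_record_reaction(model_ap(), 1L), duration = 4)
  for (fi in seq_along(base$frames))
    expect_identical(base$frames[[fi]][, 1:2], wrapped$frames[[fi]][, 1:2])
})

test_that("LAT records the linearly interpolated crossing time", {
  # scripted ramp u(t) = t sampled at dt = 0.1, threshold 0.55
  m <- model_1varpoly(k = 0)        # inert reaction
  lat <- wrap_record_lat(m, 1L, threshold = 0.55)
  g <- grid_spec(c(2L, 1L), 1)
  geom <- geometry_iso(g, 0)
  # drive u with an additive unit source: du/dt = 1 so u(t) = t exactly
  src <- source_spec(stimuli = list(
    stimulus(1L, 1, "add", shape_all(), t_on = 0, t_off = 10)))
  res <- run_simulation(lat, geom, src, sim_config(1, dt = 0.1))
  expect_equal(res$state[1, 2], 0.55, tolerance = 1e-12)

  # never crossing: sentinel stays
  res2 <- run_simulation(lat, geom, source_spec(),
                         sim_config(1, dt = 0.1))
  expect_equal(res2$state[, 2], c(-1, -1))
})

test_that("LAT keeps the most recent crossing of a two-pulse trace", {
  m <- model_1varpoly(k = 0)
  lat <- wrap_record_lat(m, 1L, threshold = 0.5)
  g <- grid_spec(c(2L, 1L), 1)
  geom <- geometry_iso(g, 0)
  pulse <- function(t_on) list(
    stimulus(1L, 1, "set", shape_all(), t_on = t_on),
    stimulus(1L, 0, "set", shape_all(), t_on = t_on + 50))
  src <- source_spec(stimuli = c(pulse(10), pulse(310)))
  res <- run_simulation(lat, geom, src, sim_config(400, dt = 0.1))
  expect_gt(res$state[1, 2], 300)       # second pulse wins
  expect_lt(res$state[1, 2], 311)
})

test_that("LDT records downward crossings", {
  m <- model_1varpoly(k = 0)
  ldt <- wrap_record_ldt(m, 1L, threshold = 0.5)
  g <- grid_spec(c(2L, 1L), 1)
  src <- source_spec(stimuli = list(
    stimulus(1L, 1, "set", shape_all(), t_on = 0),
    stimulus(1L, 0, "set", shape_all(), t_on = 5)))
  res <- run_simulation(ldt, geometry_iso(g, 0), src,
                        sim_config(10, dt = 0.1))
  expect_gte(res$state[1, 2], 4.9)
  expect_lte(res$state[1, 2], 5.0)
})

test_that("rescaling is exact for identity factors and invertible maps", {
  m <- model_ap()
  ident <- rescale_model(m, 1, 1)
  u <- c(0.4, 0.2)
  expect_identical(reaction(ident, u), reaction(m, u))

  half <- rescale_model(m, time_factor = 2)
  expect_equal(reaction(half, u), reaction(m, u) / 2, tolerance = 1e-14)

  # normalized voltage -> mV and back
  mv <- rescale_model(m, var_scale = c(100, 1), var_shift = c(-80, 0))
  expect_equal(resting_state(mv), c(-80, 0))
  u_mv <- c(100 * 0.4 - 80, 0.2)
  r_mv <- reaction(mv, u_mv)
  expect_equal(r_mv / c(100, 1), reaction(m, u), tolerance = 1e-12)
  expect_equal(mv$metadata$diffusivity_scale, 1)
  expect_equal(rescale_model(m, 2, 4)$metadata$diffusivity_scale, 8)
  expect_error(rescale_model(m, time_factor = 0),
               class = "mw_validation_error")
})

test_that("multi-model dispatch matches each submodel within its region", {
  g <- grid_spec(c(20L, 2L), 1)
  labels <- matrix(1L, 20, 2)
  labels[11:20, ] <- 2L
  ih <- inhom_field(g, labels)
  m1 <- model_ap()
  m2 <- model_ap(k = 10)
  mm <- multi_model(list(m1, m2), ih)
  U <- matrix(runif(g$n * 2), g$n, 2)
  R <- reaction(mm, U, ctx = list(labels = as.vector(labels)))
  left <- as.vector(labels) == 1L
  expect_equal(R[left, ], reaction(m1, U[left, ]))
  expect_equal(R[!left, ], reaction(m2, U[!left, ]))

  # identical submodels everywhere equal the single-model run exactly
  mm_same <- multi_model(list(model_ap(), model_ap()), ih)
  ga <- geometry_iso(g, 1, ih)
  src <- source_spec(stimuli = list(
    stimulus(1L, 1, "set", shape_cuboid(c(0, 0), c(2, 0)))))
  r_multi <- run_simulation(mm_same, ga, src, sim_config(5, dt = 0.1))
  r_single <- run_simulation(model_ap(), ga, src, sim_config(5, dt = 0.1))
  expect_identical(r_multi$state, r_single$state)

  expect_error(run_simulation(multi_model(list(m1)), geometry_iso(g, 1, ih),
                              src, sim_config(1, dt = 0.1)),
               class = "mw_validation_error")  # label 2 has no submodel
})

test_that("exterior vertices are never evaluated and stay at rest", {
  g <- grid_spec(c(10L, 4L), 1)
  labels <- matrix(1L, 10, 4)
  labels[4:6, 2:3] <- 0L
  ih <- inhom_field(g, labels)
  res <- run_simulation(model_ap(), geometry_iso(g, 1, ih),
                        source_spec(stimuli = list(
                          stimulus(1L, 1, "set",
                                   shape_cuboid(c(0, 0), c(2, 0))))),
                        sim_config(5, dt = 0.1))
  ext <- as.vector(labels) == 0L
  expect_equal(res$state[ext, ], matrix(0, sum(ext), 2))
})
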