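bilinear_eval <- function(c4, s, t) {
  c4[1] * (1 - s) * (1 - t) + c4[2] * s * (1 - t) +
    c4[3] * (1 - s) * t + c4[4] * s * t
}

test_that("linear corner data give the exact crossing point", {
  # f = s - 0.5, g = t - 0.5 as corner values
  f <- c(-0.5, 0.5, -0.5, 0.5)
  g <- c(-0.5, -0.5, 0.5, 0.5)
  pts <- bilinear_face_intersection(f, g, 0, 0)
  expect_equal(nrow(pts), 1L)
  expect_equal(unname(pts[1, ]), c(0.5, 0.5))
})

test_that("parallel isolines yield no intersection", {
  f <- c(-0.5, 0.5, -0.5, 0.5)
  g <- f + 1
  expect_equal(nrow(bilinear_face_intersection(f, g, 0, 0)), 0L)
  # a constant interpolant equal to its isovalue is a line, not a point
  expect_equal(nrow(bilinear_face_intersection(rep(0, 4), g, 0, 0)), 0L)
})

test_that("random faces match the isoline-walk oracle", {
  set.seed(123)
  n_two <- 0L
  for (i in 1:500) {
    f <- rnorm(4); g <- rnorm(4)
    pts <- bilinear_face_intersection(f, g, 0, 0)
    ref <- face_scan_oracle(f, g, 0, 0)
    expect_equal(nrow(pts), nrow(ref),
                 label = sprintf("face %d count", i))
    if (nrow(pts)) {
      o <- order(pts[, 1]); or <- order(ref[, 1])
      expect_lt(max(abs(pts[o, , drop = FALSE] -
                          ref[or, , drop = FALSE])), 1e-10)
      for (r in seq_len(nrow(pts))) {
        expect_lt(abs(bilinear_eval(f, pts[r, 1], pts[r, 2])), 1e-10)
        expect_lt(abs(bilinear_eval(g, pts[r, 1], pts[r, 2])), 1e-10)
      }
    }
    if (nrow(pts) == 2L) n_two <- n_two + 1L
  }
  expect_gt(n_two, 0L)   # the two-solution branch is exercised
})

test_that("a constructed isoline crossing is located within half a voxel", {
  g3 <- grid_spec(c(11, 11), 1)
  pos <- grid_positions(g3)
  cx <- 5.3; cy <- 4.7
  tips <- detect_tips(list(pos[, 1] - cx, pos[, 2] - cy), g3, iso = c(0, 0))
  expect_gte(nrow(tips), 1L)
  expect_lt(abs(mean(tips$x) - cx), 0.5)
  expect_lt(abs(mean(tips$y) - cy), 0.5)
})

test_that("planar waves carry no phase singularities", {
  sc <- scenario_planar_wave(duration = 20)
  res <- run_scenario(sc)
  expect_true(all(vapply(res$tipdata, nrow, 1L) == 0L))
})

test_that("out-of-range isovalues warn and return no tips", {
  g <- grid_spec(c(5, 5), 1)
  U <- matrix(runif(50), 25, 2)
  expect_warning(tips <- detect_tips(U, g, iso = c(10, 10)),
                 "outside the observed range")
  expect_equal(nrow(tips), 0L)
})

test_that("all coordinate-plane families are scanned in 3D", {
  # a filament line along z: u and v vary only in x, y => crossings lie in
  # xy-faces at every z level, none in xz / yz planes
  g <- grid_spec(c(7, 7, 4), 1)
  pos <- grid_positions(g)
  tips <- detect_tips(list(pos[, 1] - 3.4, pos[, 2] - 2.6), g,
                      iso = c(0, 0))
  expect_equal(sort(unique(tips$plane)), "xy")
  expect_equal(nrow(tips), 4L)            # one per z level
  expect_equal(sort(tips$z), 0:3)
  # a diagonal pair varying in (x, z): crossings live in xz faces
  tips2 <- detect_tips(list(pos[, 1] - 3.4, pos[, 3] - 1.5), g,
                       iso = c(0, 0))
  expect_true(all(tips2$plane == "xz"))
})

test_that("detection ignores exterior relabeling away from the tip", {
  g <- grid_spec(c(11, 11), 1)
  pos <- grid_positions(g)
  layers <- list(pos[, 1] - 5.3, pos[, 2] - 4.7)
  t0 <- detect_tips(layers, g, iso = c(0, 0))
  lab <- matrix(1L, 11, 11); lab[10:11, 10:11] <- 0L
  t1 <- detect_tips(layers, g, iso = c(0, 0), inhom = inhom_field(g, lab))
  expect_equal(t0[, c("x", "y")], t1[, c("x", "y")])
})

test_that("trajectory linking follows births, deaths and the greedy rule", {
  mk <- function(x, y) data.frame(time = NA_real_, x = x, y = y, z = 0,
                                  plane = "xy", i = 1L, j = 1L, k = 1L,
                                  s = 0, t = 0, iso_f = 0, iso_g = 0)
  # single stationary tip over 10 frames
  frames <- replicate(10, mk(2, 2), simplify = FALSE)
  tr <- link_trajectories(frames, max_link_distance = 1, times = 1:10)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$points), 10L)
  expect_true(tr[[1]]$open)
  expect_equal(tr[[1]]$birth, 1)

  # tip disappearing at frame 5: death time = frame-5 time
  frames2 <- c(replicate(4, mk(2, 2), simplify = FALSE),
               replicate(3, mk(2, 2)[0, ], simplify = FALSE))
  tr2 <- link_trajectories(frames2, 1, times = 1:7)
  expect_false(tr2[[1]]$open)
  expect_equal(tr2[[1]]$death, 5)

  # two tips listed in swapped order between frames: the greedy rule keeps
  # each trajectory at its own position instead of following the listing
  fA <- rbind(mk(0, 0), mk(10, 0))
  fB <- rbind(mk(10, 0), mk(0, 0))
  tr3 <- link_trajectories(list(fA, fB), max_link_distance = 2,
                           times = 1:2)
  expect_length(tr3, 2L)
  for (tb in tr3) expect_equal(diff(tb$points$x), 0)
  # tips jumping beyond the radius break the trajectories: deaths + births
  fC2 <- rbind(mk(5, 0), mk(15, 0))
  tr3b <- link_trajectories(list(fA, fC2), max_link_distance = 2,
                            times = 1:2)
  expect_length(tr3b, 4L)
  expect_equal(sum(vapply(tr3b, function(x) x$open, TRUE)), 2L)
  # within the radius the greedy rule matches nearest-first
  fC <- rbind(mk(0.4, 0), mk(9.0, 0))
  tr4 <- link_trajectories(list(fA, fC), max_link_distance = 2,
                           times = 1:2)
  expect_length(tr4, 2L)
  expect_equal(nrow(tr4[[1]]$points), 2L)
  expect_equal(nrow(tr4[[2]]$points), 2L)
})

test_that("S1S2 tip counts start at zero and change by small jumps", {
  sc <- scenario_s1s2_spiral()
  res <- run_scenario(sc, duration = 150)
  counts <- vapply(res$tipdata, nrow, 1L)
  t2 <- res$trigger_log[[1]]$t
  expect_true(all(counts[res$frame_times < t2] == 0L))
  expect_true(any(counts[res$frame_times > t2] >= 1L))
  # rotor bookkeeping: between frames the count changes by 0, +-1
  # (boundary events) or +-2 (pair creation/annihilation)
  expect_true(all(abs(diff(counts)) <= 2))
  # the induced rotor persists: link its trajectory across frames
  # 5 ms between frames: a circulating tip moves several mm per gap
  tr <- link_trajectories(res$tipdata, max_link_distance = 8,
                          times = res$frame_times)
  lifespans <- vapply(tr, function(x)
    diff(range(x$points$time)), 1)
  expect_gt(max(lifespans), 50)
})
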