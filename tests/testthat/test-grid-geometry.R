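test_that("grid_spec validates its invariants and places vertices", {
  g <- grid_spec(c(4, 3), spacing = c(0.5, 1), origin = c(1, 2))
  expect_equal(g$n, 12L)
  pos <- grid_positions(g)
  expect_equal(pos[1, ], c(1, 2))          # first vertex at the origin
  expect_equal(pos[2, ], c(1.5, 2))        # x fastest
  expect_equal(pos[g$n, ], c(1 + 3 * 0.5, 2 + 2 * 1))
  expect_error(grid_spec(c(0, 3), 1), class = "mw_validation_error")
  expect_error(grid_spec(c(3, 3), c(1, -1)), class = "mw_validation_error")
})

test_that("fiber frames must be orthonormal", {
  expect_silent(fiber_field(c(1, 0, 0), c(0, 1, 0)))
  expect_error(fiber_field(c(1, 0, 0), c(1, 0, 0)),
               class = "mw_validation_error")
  expect_error(fiber_field(c(2, 0, 0), c(0, 1, 0)),
               class = "mw_validation_error")
})

test_that("diffusion tensor from fibers matches the outer-product form", {
  fib <- fiber_field(c(1, 0, 0), c(0, 1, 0))
  D <- build_diffusion_tensor(fib, diffusion_aniso(4, 1, 1, fib))
  expect_equal(D[1, , ], diag(c(4, 1, 1)))

  # equal diffusivities give d * Identity for any orthonormal frame
  v1 <- c(1, 2, 2) / 3
  v2 <- c(2, 1, -2) / 3
  fib2 <- fiber_field(v1, v2)
  D2 <- build_diffusion_tensor(fib2, diffusion_aniso(0.7, 0.7, 0.7, fib2))
  expect_equal(D2[1, , ], 0.7 * diag(3), tolerance = 1e-12)

  # single outer product
  e <- c(1, 1, 0) / sqrt(2)
  fib3 <- fiber_field(e, c(0, 0, 1))
  D3 <- build_diffusion_tensor(fib3, diffusion_aniso(2, 0, 0, fib3))
  expect_equal(D3[1, , ], rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 0)),
               tolerance = 1e-12)
})

test_that("isotropic stencil weights follow D/dx^2 with zero-flux closure", {
  g <- grid_spec(c(5, 5), 1)
  st <- isotropic_stencil(g, 1)
  W <- as.matrix(st$W)
  center <- 13L                   # (3, 3)
  expect_equal(W[center, center], -4)
  expect_equal(sort(W[center, W[center, ] > 0]), rep(1, 4))

  g1 <- grid_spec(9L, 0.5)
  W1 <- as.matrix(isotropic_stencil(g1, 1)$W)
  expect_equal(W1[5, 4], 4)       # 1/dx^2 scaling
  expect_equal(W1[5, 5], -8)

  # boundary vertex: the face to the missing neighbor carries zero flux,
  # so only the surviving neighbor weight remains
  g2 <- grid_spec(3L, 1)
  W2 <- as.matrix(isotropic_stencil(g2, 1)$W)
  expect_equal(W2[1, ], c(-1, 1, 0))
  expect_equal(W2[3, ], c(0, 1, -1))
})

test_that("apply_diffusion annihilates constants and conserves totals", {
  set.seed(11)
  g <- grid_spec(c(8, 6), c(0.7, 0.9))
  st <- isotropic_stencil(g, 0.8)
  expect_equal(max(abs(apply_diffusion(st, matrix(3.7, 8, 6)))), 0)

  # x^2 on a 1D interior: exact second difference = 2
  g1 <- grid_spec(10L, 1)
  x <- grid_positions(g1)[, 1]
  y <- apply_diffusion(isotropic_stencil(g1, 1), x^2)
  expect_equal(y[2:9], rep(2, 8))

  # conservation for random fields and random masks
  for (seed in 1:5) {
    set.seed(seed)
    mask <- matrix(rbinom(48, 1, 0.8), 8, 6)
    if (!any(mask > 0)) mask[1, 1] <- 1L
    stm <- isotropic_stencil(g, 1.3, inhom = inhom_field(g, mask))
    u <- rnorm(g$n)
    y <- apply_diffusion(stm, u)
    expect_lt(abs(sum(y)), 1e-9 * max(1, sum(abs(y))))
    expect_equal(y[as.vector(mask) == 0], rep(0, sum(mask == 0)))
  }
})

test_that("CFL bound reproduces the closed form and its degenerate cases", {
  g <- grid_spec(c(10, 10), 1)
  expect_equal(cfl_bound(g, diffusion_iso(1), 1), 0.25)
  g3 <- grid_spec(c(5, 5, 5), 0.2)
  expect_equal(cfl_bound(g3, diffusion_iso(0.1), 1), 1 / 15)
  expect_identical(cfl_bound(g, diffusion_iso(1), 0), Inf)   # nothing diffuses
  expect_identical(cfl_bound(g, diffusion_iso(0), 1), Inf)   # reaction-only
  # stencil-weight bound agrees with the closed form on interior-dominated
  # isotropic grids
  st <- isotropic_stencil(g, 1)
  expect_equal(st$cfl_dt, 0.25)
})

test_that("orthotropic stencil reduces exactly to the isotropic one", {
  g <- grid_spec(c(7, 6), c(0.8, 1.1))
  set.seed(3)
  mask <- matrix(rbinom(42, 1, 0.85), 7, 6)
  mask[2, 2] <- 1L
  ih <- inhom_field(g, mask)
  iso <- isotropic_stencil(g, 0.6, inhom = ih)
  ort <- orthotropic_stencil(g, tensor_constant(diag(c(0.6, 0.6))),
                             inhom = ih)
  expect_identical(as.matrix(ort$W), as.matrix(iso$W))  # bit-for-bit
})

test_that("mixed-derivative terms reproduce the analytic operator", {
  # u = x y with constant D = [[1,1],[1,1]]: div(D grad u) = 2 d2u/dxdy = 2
  g <- grid_spec(c(8, 8), 1)
  st <- orthotropic_stencil(g, tensor_constant(rbind(c(1, 1), c(1, 1))))
  pos <- grid_positions(g)
  y <- matrix(apply_diffusion(st, pos[, 1] * pos[, 2]), 8, 8)
  expect_equal(y[3:6, 3:6], matrix(2, 4, 4), tolerance = 1e-12)
})

test_that("stencil application matches the dense divergence-form oracle", {
  for (case in 1:6) {
    set.seed(100 + case)
    sh <- if (case <= 3) c(sample(6:16, 1), sample(5:12, 1))
          else c(sample(5:9, 1), sample(4:8, 1), sample(3:8, 1))
    g <- grid_spec(sh, runif(length(sh), 0.4, 1.2))
    tens <- random_psd_tensor(g, 200 + case)
    mask <- array(rbinom(g$n, 1, 0.9), dim = sh)
    mask[1] <- 1L
    ih <- inhom_field(g, mask)
    st <- orthotropic_stencil(g, tens, inhom = ih)
    L <- dense_divergence_matrix(g, unclass(tens), as.vector(mask) > 0)
    u <- rnorm(g$n)
    y1 <- apply_diffusion(st, u)
    y2 <- as.numeric(L %*% u)
    expect_lt(max(abs(y1 - y2)), 1e-10 * max(1, max(abs(y2))))
    expect_lt(abs(sum(y1)), 1e-9 * max(1, sum(abs(y1))))
  }
})

test_that("mirroring the fiber field mirrors the operator output", {
  g <- grid_spec(c(9, 7), 1)
  set.seed(42)
  theta <- matrix(runif(g$n, 0, pi / 3), 9, 7)
  make_tensor <- function(th) {
    n <- length(th)
    D <- array(0, c(n, 2, 2))
    ef <- cbind(cos(th), sin(th))
    es <- cbind(-sin(th), cos(th))
    for (a in 1:2) for (b in 1:2)
      D[, a, b] <- 2 * ef[, a] * ef[, b] + 0.5 * es[, a] * es[, b]
    structure(D, class = "tensor_field")
  }
  flipx <- function(m) m[9:1, ]
  th <- as.vector(theta)
  # reflect across x: angle -> pi - theta mirrored in x
  th_m <- as.vector(-flipx(theta))
  st <- orthotropic_stencil(g, make_tensor(th))
  st_m <- orthotropic_stencil(g, make_tensor(th_m))
  u <- matrix(rnorm(g$n), 9, 7)
  y <- matrix(apply_diffusion(st, u), 9, 7)
  y_m <- matrix(apply_diffusion(st_m, flipx(u)), 9, 7)
  expect_equal(flipx(y_m), y, tolerance = 1e-12)
})

test_that("degenerate and invalid inputs are rejected or handled", {
  g <- grid_spec(c(4, 4), 1)
  expect_error(apply_diffusion(isotropic_stencil(g, 1), rnorm(7)),
               class = "mw_validation_error")
  z <- isotropic_stencil(g, 0)
  expect_equal(max(abs(apply_diffusion(z, rnorm(16)))), 0)   # zero operator
  expect_error(orthotropic_stencil(g, tensor_constant(diag(3))),
               class = "mw_validation_error")                # dim mismatch
  expect_error(tensor_constant(rbind(c(1, 2), c(0, 1))),
               class = "mw_validation_error")                # not symmetric
})
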