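# Independent oracles, written as plain scalar loops so they share no code
# path with the package's vectorized assembly.

# Dense divergence-form diffusion matrix: face-centered fluxes, tensor
# entries averaged to face midpoints, tangential derivatives as central
# differences averaged over the face endpoints (one-sided next to
# non-interior vertices). Zero flux through any face touching a
# non-interior vertex.
dense_divergence_matrix <- function(grid, Drows, interior) {
  n <- grid$n
  N <- grid$N
  sh <- grid$shape
  dx <- grid$spacing
  idx <- arrayInd(seq_len(n), .dim = sh)
  lin <- function(ii) {
    if (any(ii < 1L) || any(ii > sh)) return(NA_integer_)
    l <- ii[1]
    mult <- 1
    for (a in seq_len(N)[-1]) {
      mult <- mult * sh[a - 1]
      l <- l + (ii[a] - 1) * mult
    }
    as.integer(l)
  }
  intr <- function(v) !is.na(v) && interior[v]
  L <- matrix(0, n, n)
  # derivative coefficients of u along axis b at vertex v
  dcoef <- function(v, b) {
    ip <- idx[v, ]; ip[b] <- ip[b] + 1L
    im <- idx[v, ]; im[b] <- im[b] - 1L
    vp <- lin(ip); vm <- lin(im)
    hp <- intr(vp); hm <- intr(vm)
    if (hp && hm) {
      list(cols = c(vp, vm), w = c(1, -1) / (2 * dx[b]))
    } else if (hp) {
      list(cols = c(vp, v), w = c(1, -1) / dx[b])
    } else if (hm) {
      list(cols = c(v, vm), w = c(1, -1) / dx[b])
    } else list(cols = integer(0), w = numeric(0))
  }
  for (v in seq_len(n)) {
    if (!interior[v]) next
    for (a in seq_len(N)) {
      for (sgn in c(1L, -1L)) {
        jn <- idx[v, ]; jn[a] <- jn[a] + sgn
        j <- lin(jn)
        if (!intr(j)) next            # zero flux through this face
        # face between v and j; flux taken outward along +axis convention:
        # F = Daa (u_j - u_v) sgn / dx_a + sum_b Dab * avg tangential
        # contribution to dv: sgn * F / dx_a
        Daa <- 0.5 * (Drows[v, a, a] + Drows[j, a, a])
        L[v, j] <- L[v, j] + Daa / (dx[a] * dx[a])
        L[v, v] <- L[v, v] - Daa / (dx[a] * dx[a])
        for (b in seq_len(N)) {
          if (b == a) next
          Dab <- 0.5 * (Drows[v, a, b] + Drows[j, a, b])
          if (Dab == 0) next
          for (endp in c(v, j)) {
            dc <- dcoef(endp, b)
            for (q in seq_along(dc$cols)) {
              L[v, dc$cols[q]] <- L[v, dc$cols[q]] +
                sgn * Dab * 0.5 * dc$w[q] / dx[a]
            }
          }
        }
      }
    }
  }
  L
}

# Independent transcription of the three-current Fenton-Karma reaction
# (scalar form, Heaviside as if/else).
fk_reference <- function(u, v, w, p) {
  H <- function(x) if (x >= 0) 1 else 0
  Jfi <- -v / p$tau_d * H(u - p$u_c) * (1 - u) * (u - p$u_c)
  Jso <- u / p$tau_0 * H(p$u_c - u) + H(u - p$u_c) / p$tau_r
  Jsi <- -w / (2 * p$tau_si) * (1 + tanh(p$k * (u - p$u_csi)))
  tvm <- if (u >= p$u_v) p$tau_vm1 else p$tau_vm2
  dv <- if (u >= p$u_c) -v / p$tau_vp else (1 - v) / tvm
  dw <- if (u >= p$u_c) -w / p$tau_wp else (1 - w) / p$tau_wm
  c(-(Jfi + Jso + Jsi), dv, dw)
}

# Face-scan oracle for bilinear isoline intersections: walk the f-isoline
# parameterized by s (t solved linearly from f), bracket sign changes of
# the g residual on a dense s grid, refine with uniroot.
face_scan_oracle <- function(f, g, fiso = 0, giso = 0, ns = 2001) {
  a0 <- f[1] - fiso; a1 <- f[2] - f[1]; a2 <- f[3] - f[1]
  a3 <- f[4] - f[2] - f[3] + f[1]
  b0 <- g[1] - giso; b1 <- g[2] - g[1]; b2 <- g[3] - g[1]
  b3 <- g[4] - g[2] - g[3] + g[1]
  tf <- function(s) -(a0 + a1 * s) / (a2 + a3 * s)
  h <- function(s) b0 + b1 * s + (b2 + b3 * s) * tf(s)
  ss <- seq(0, 1, length.out = ns)
  hv <- vapply(ss, h, 1)
  tv <- vapply(ss, tf, 1)
  out <- NULL
  for (i in seq_len(ns - 1)) {
    ok_t <- is.finite(tv[i]) && is.finite(tv[i + 1]) &&
      max(tv[i], tv[i + 1]) >= -1e-6 && min(tv[i], tv[i + 1]) <= 1 + 1e-6
    if (!ok_t || !is.finite(hv[i]) || !is.finite(hv[i + 1])) next
    if (hv[i] == 0) {
      s <- ss[i]
    } else if (hv[i] * hv[i + 1] < 0) {
      s <- suppressWarnings(
        stats::uniroot(h, c(ss[i], ss[i + 1]), tol = 1e-14)$root)
    } else next
    t <- tf(s)
    if (t >= -1e-9 && t <= 1 + 1e-9)
      out <- rbind(out, c(max(0, min(1, s)), max(0, min(1, t))))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else unique(round(out, 12))
}

# small helper: random smooth PSD tensor field on a grid
random_psd_tensor <- function(grid, seed) {
  set.seed(seed)
  N <- grid$N
  n <- grid$n
  A <- matrix(rnorm(N * N), N)
  base <- crossprod(A) + diag(N) * 0.3
  ps <- grid_positions(grid)
  mod <- 1 + 0.4 * sin(ps[, 1]) + 0.3 * cos(ps[, min(2, N)])
  D <- array(0, c(n, N, N))
  for (a in seq_len(N)) for (b in seq_len(N)) D[, a, b] <- base[a, b] * mod
  structure(D, class = "tensor_field")
}

# space-clamped trajectories by dense RK4 sub-stepping, vectorized over
# starts (rows of U0); returns the running min/max per variable so
# containment can be asserted over the whole trajectory
clamped_envelope <- function(model, U0, t_end, dt = 0.05) {
  U <- U0
  lo <- apply(U, 2, min); hi <- apply(U, 2, max)
  f <- function(U) reaction(model, U)
  for (i in seq_len(ceiling(t_end / dt))) {
    k1 <- f(U); k2 <- f(U + dt / 2 * k1); k3 <- f(U + dt / 2 * k2)
    k4 <- f(U + dt * k3)
    U <- U + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    lo <- pmin(lo, apply(U, 2, min))
    hi <- pmax(hi, apply(U, 2, max))
  }
  list(lo = lo, hi = hi, final = U)
}
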