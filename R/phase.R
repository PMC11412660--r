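#' Activation-time phase
#'
#' Maps local activation times to a phase on the circle:
#' `phi(t, x) = wrap(2 pi (t - LAT(x)) / T)` with values in (-pi, pi]
#' (the half-period point maps to +pi by convention). Vertices still at the
#' "never activated" sentinel are excluded (NA).
#'
#' @param lat LAT field (array or vector), ms.
#' @param t current time, ms.
#' @param T activation period, ms (> 0).
#' @param sentinel the "never activated" marker in `lat` (default -1).
#' @return phase field in (-pi, pi], NA at sentinel vertices.
#' @export
activation_phase <- function(lat, t, T, sentinel = -1) {
  if (T <= 0) stop_validation("period T must be > 0")
  act <- lat != sentinel
  if (!any(act)) stop_validation("no activated vertices (all LAT at sentinel)")
  w <- (2 * pi * (t - lat) / T) %% (2 * pi)
  phi <- ifelse(w > pi, w - 2 * pi, w)
  phi[!act] <- NA_real_
  if (!is.null(dim(lat))) dim(phi) <- dim(lat)
  phi
}

#' Phase-defect density (cosine method)
#'
#' Scores how discontinuous the phase field is at each vertex:
#' `rho(x) = mean over interior nearest neighbors y of
#' (1 - cos(phi(y) - phi(x))) / 2`. A locally smooth phase gives ~0
#' (second order in the local phase increment); across a pi jump the
#' cross-boundary neighbor terms contribute 1, so rho rises toward 1 along
#' phase-defect lines. Exterior or NA-phase vertices are excluded from the
#' neighbor sets; a vertex with no usable neighbor scores 0.
#'
#' @param phase phase field (array of the grid's shape), radians.
#' @param grid a [grid_spec()].
#' @param inhom optional [inhom_field()].
#' @return array of the grid's shape with values in `[0, 1]` (0 at
#'   exterior vertices).
#' @export
phase_defect_density <- function(phase, grid, inhom = NULL) {
  inhom <- as_inhom(grid, inhom)
  ok <- as.vector(inhom) > 0L & is.finite(as.numeric(phase))
  phi <- as.numeric(phase)
  idx <- grid_indices(grid)
  st <- x_strides(grid)
  acc <- numeric(grid$n)
  cnt <- numeric(grid$n)
  for (a in seq_len(grid$N)) {
    for (s in c(-1L, 1L)) {
      inb <- if (s > 0L) idx[, a] < grid$shape[a] else idx[, a] > 1L
      i <- which(ok & inb)
      j <- i + s * st[a]
      keep <- ok[j]
      i <- i[keep]; j <- j[keep]
      if (!length(i)) next
      acc[i] <- acc[i] + (1 - cos(phi[j] - phi[i])) / 2
      cnt[i] <- cnt[i] + 1
    }
  }
  rho <- numeric(grid$n)
  nz <- cnt > 0
  rho[nz] <- acc[nz] / cnt[nz]
  rho[!ok] <- 0
  if (!is.null(dim(phase))) dim(rho) <- dim(phase) else dim(rho) <- grid$shape
  rho
}
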