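#' Spatial shapes (characteristic functions)
#'
#' A shape is a characteristic function chi(x) in \[0, 1\] over positions in
#' mm: 1 inside, 0 outside, intermediate values only for smoothed or
#' array-defined shapes. Shapes delimit where stimuli act.
#'
#' Conventions: a half-plane's boundary (zero dot product with the outward
#' normal) counts as inside; cuboid bounds are inclusive on both corners; a
#' cuboid whose two corners agree along some axis leaves that axis
#' unconstrained (so a rectangle given in the first two coordinates selects
#' a full slab of a 3D grid).
#'
#' @param x position vector (mm) or matrix of positions (rows).
#' @param shape an `mw_shape`.
#' @return [shape_indicator()]: chi value(s) in \[0, 1\].
#' @name shapes
NULL

new_shape <- function(name, chi) {
  structure(list(name = name, chi = chi), class = "mw_shape")
}

as_pos_matrix <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x

#' @rdname shapes
#' @export
shape_indicator <- function(shape, x) {
  v <- shape$chi(as_pos_matrix(x))
  if (any(v < 0 | v > 1)) stop_validation("characteristic function left [0, 1]")
  if (is.null(dim(x))) v[1] else v
}

#' @rdname shapes
#' @param radii,radius semi-axes / radius, mm.
#' @param center center position, mm.
#' @param angles Euler angles (z-y-x intrinsic), radians; rotates the
#'   ellipsoid axes.
#' @export
shape_ellipsoid <- function(radii, center = rep(0, length(radii)),
                            angles = c(0, 0, 0)) {
  R <- euler_rotation(angles, length(radii))
  new_shape("ellipsoid", function(P) {
    d <- sweep(P[, seq_along(radii), drop = FALSE], 2, center, `-`) %*% t(R)
    q <- sweep(d, 2, radii, `/`)
    (rowSums(q^2) <= 1) + 0
  })
}

euler_rotation <- function(angles, N) {
  if (N < 3 || all(angles == 0)) return(diag(N))
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

#' @rdname shapes
#' @export
shape_sphere <- function(radius, center) {
  new_shape("sphere", function(P) {
    d <- sweep(P[, seq_along(center), drop = FALSE], 2, center, `-`)
    (rowSums(d^2) <= radius^2) + 0
  })
}

#' @rdname shapes
#' @export
shape_ellipse_xy <- function(radii, center = c(0, 0)) {
  new_shape("ellipse_xy", function(P) {
    d <- sweep(P[, 1:2, drop = FALSE], 2, center[1:2], `-`)
    q <- sweep(d, 2, radii[1:2], `/`)
    (rowSums(q^2) <= 1) + 0
  })
}

#' @rdname shapes
#' @export
shape_cylinder_z <- function(radius, center = c(0, 0)) {
  new_shape("cylinder_z", function(P) {
    d <- sweep(P[, 1:2, drop = FALSE], 2, center[1:2], `-`)
    (rowSums(d^2) <= radius^2) + 0
  })
}

#' @rdname shapes
#' @param corner1,corner2 two opposing corners, mm.
#' @export
shape_cuboid <- function(corner1, corner2) {
  lo <- pmin(corner1, corner2)
  hi <- pmax(corner1, corner2)
  free <- lo == hi   # degenerate axes are unconstrained
  new_shape("cuboid", function(P) {
    ok <- rep(TRUE, nrow(P))
    for (a in seq_along(lo)) {
      if (free[a] || a > ncol(P)) next
      ok <- ok & P[, a] >= lo[a] & P[, a] <= hi[a]
    }
    ok + 0
  })
}

#' @rdname shapes
#' @param origin a point on the dividing plane, mm.
#' @param normal outward normal; points with `(x - origin) . normal <= 0`
#'   are inside.
#' @export
shape_halfplane <- function(origin, normal) {
  new_shape("halfplane", function(P) {
    d <- sweep(P[, seq_along(origin), drop = FALSE], 2, origin, `-`)
    (as.numeric(d %*% normal) <= 0) + 0
  })
}

#' @rdname shapes
#' @param grid a [grid_spec()].
#' @param values array of chi values (grid shape), in \[0, 1\]; positions
#'   evaluate to the nearest vertex's value.
#' @export
shape_from_array <- function(grid, values) {
  if (!identical(as.integer(dim(values)), grid$shape))
    stop_validation("shape array must have the grid's shape")
  if (any(values < 0 | values > 1))
    stop_validation("shape array values must lie in [0, 1]")
  v <- as.numeric(values)
  new_shape("from_array", function(P) {
    idx <- vapply(seq_len(nrow(P)), function(r)
      grid_nearest_vertex(grid, P[r, ]), 1L)
    v[idx]
  })
}

#' @rdname shapes
#' @export
shape_all <- function() new_shape("all", function(P) rep(1, nrow(P)))

#' Stimulus definition
#'
#' A stimulus assigns (`set` mode) or injects (`add` mode, current-like)
#' values into selected state variables inside a shape during an active time
#' window, optionally modulated by an amplitude function `a(t)`:
#' set mode blends `u <- (1 - chi) u + chi (value a(t))`; add mode
#' contributes `value a(t) chi(x)` to du/dt inside the window. A window with
#' `t_off == t_on` is an instantaneous set applied once, at the first
#' processed time at or after `t_on`.
#'
#' @param vars target variable indices.
#' @param values one value per target variable (state units for `set`,
#'   units/ms for `add`).
#' @param mode `"set"` or `"add"`.
#' @param shape an `mw_shape` (default: everywhere).
#' @param t_on,t_off active window, ms.
#' @param amplitude function of time, scalar multiplier (default constant 1).
#' @export
stimulus <- function(vars, values, mode = c("set", "add"),
                     shape = shape_all(), t_on = 0, t_off = t_on,
                     amplitude = NULL) {
  mode <- match.arg(mode)
  if (length(values) != length(vars))
    stop_validation("one value per target variable required")
  if (t_off < t_on) stop_validation("t_off must be >= t_on")
  structure(list(vars = as.integer(vars), values = as.numeric(values),
                 mode = mode, shape = shape, t_on = t_on, t_off = t_off,
                 amplitude = if (is.null(amplitude)) function(t) 1
                             else amplitude),
            class = "mw_stimulus")
}

# chi evaluated on the grid, zeroed on exterior vertices (stimulating an
# exterior vertex is a no-op)
stimulus_chi <- function(stim, grid, interior) {
  chi <- shape_indicator(stim$shape, grid_positions(grid))
  chi[!interior] <- 0
  chi
}

stimulus_active <- function(stim, t, tol = 1e-9) {
  t >= stim$t_on - tol & t <= stim$t_off + tol
}

#' Apply a set-mode stimulus to a state matrix
#'
#' @param stim a [stimulus()] with `mode = "set"`.
#' @param state n x M state matrix.
#' @param grid the [grid_spec()] the state lives on.
#' @param t time, ms (must lie in the active window for any effect).
#' @param interior logical interior mask (exterior vertices are untouched).
#' @param chi optional precomputed indicator (vertex vector).
#' @return the blended state matrix.
#' @export
apply_stimulus <- function(stim, state, grid, t, interior = NULL,
                           chi = NULL) {
  if (stim$mode != "set")
    stop_validation("apply_stimulus() handles set-mode stimuli; add mode is folded into the rhs")
  if (!stimulus_active(stim, t)) return(state)
  if (is.null(interior)) interior <- rep(TRUE, grid$n)
  if (is.null(chi)) chi <- stimulus_chi(stim, grid, interior)
  a <- stim$amplitude(t)
  for (j in seq_along(stim$vars)) {
    v <- stim$vars[j]
    state[, v] <- (1 - chi) * state[, v] + chi * (stim$values[j] * a)
  }
  state
}

#' Condition-driven trigger
#'
#' Encapsulates when to execute an action: the condition is evaluated every
#' step on each domain partition; the coordination mode aggregates the
#' per-partition results (`any` partition, `all` partitions, a `specific`
#' partition, or `each` — fire independently per partition). The action runs
#' on the false-to-true transition; one-shot triggers fire at most once. In
#' a single-partition run all modes coincide.
#'
#' @param condition function `(state, t, rows)` returning `TRUE`/`FALSE`;
#'   `rows` are the vertex indices owned by the partition under evaluation.
#' @param action function `(sim, t)` executed on firing; `sim` is the
#'   running simulation environment (see [run_simulation()]).
#' @param mode coordination mode.
#' @param partition partition index for `mode = "specific"`.
#' @param one_shot fire at most once (default TRUE).
#' @export
trigger <- function(condition, action,
                    mode = c("any", "all", "each", "specific"),
                    partition = 1L, one_shot = TRUE) {
  mode <- match.arg(mode)
  structure(list(condition = condition, action = action, mode = mode,
                 partition = as.integer(partition), one_shot = one_shot),
            class = "mw_trigger")
}

#' Threshold-crossing trigger condition at a sensor vertex
#'
#' @param grid a [grid_spec()].
#' @param pos sensor position, mm (snapped to the nearest vertex).
#' @param var monitored variable index.
#' @param threshold crossing level.
#' @param direction `"up"` becomes true once the value is at/above the
#'   threshold; `"down"` becomes true when the value drops back below the
#'   threshold after having been above it (a waveback passage), so a resting
#'   vertex does not satisfy it spuriously. The trigger machinery turns the
#'   condition into an edge (false-to-true) event.
#' @return a condition closure for [trigger()]; carries the sensor vertex as
#'   attribute `vertex`.
#' @export
condition_threshold <- function(grid, pos, var, threshold,
                                direction = c("up", "down")) {
  direction <- match.arg(direction)
  vtx <- grid_nearest_vertex(grid, pos)
  armed <- FALSE
  f <- function(state, t, rows) {
    if (!(vtx %in% rows)) return(FALSE)
    u <- state[vtx, var]
    if (direction == "up") return(u >= threshold)
    if (u >= threshold) armed <<- TRUE
    armed && u < threshold
  }
  attr(f, "vertex") <- vtx
  f
}

#' Scheduled action
#'
#' Runs `action(sim, t)` exactly once, at the first step whose time reaches
#' `t_exec`. Events scheduled for the same time run in registration order.
#' @param t_exec execution time, ms (>= 0).
#' @param action function `(sim, t)`.
#' @export
schedule_event <- function(t_exec, action) {
  if (t_exec < 0) stop_validation("t_exec must be >= 0")
  structure(list(t_exec = t_exec, action = action), class = "mw_event")
}

#' Bundle of stimuli, triggers and scheduled events
#'
#' @param stimuli list of [stimulus()] objects.
#' @param triggers list of [trigger()] objects.
#' @param events list of [schedule_event()] registrations.
#' @export
source_spec <- function(stimuli = list(), triggers = list(),
                        events = list()) {
  structure(list(stimuli = stimuli, triggers = triggers, events = events),
            class = "mw_source")
}

#' S1S2 cross-field stimulation protocol
#'
#' Applies the S1 stimulus at its own start time (typically a planar wave at
#' t = 0); a threshold trigger at a sensor vertex launches the S2 stimulus
#' (typically a half-plane behind the S1 waveback) when the condition fires.
#' In 2D excitable media this is the standard spiral-induction protocol: S2
#' depolarizes half the domain just as the S1 waveback clears it, leaving a
#' free wave end that curls into a rotor.
#'
#' @param s1 the S1 [stimulus()].
#' @param s2 the S2 [stimulus()]; its window is interpreted relative to the
#'   trigger firing time.
#' @param grid a [grid_spec()].
#' @param sensor_pos sensor position, mm.
#' @param var,threshold,direction the trigger condition (default: downward
#'   crossing, i.e. the waveback passing the sensor).
#' @return an `mw_source` implementing the protocol.
#' @export
s1s2_protocol <- function(s1, s2, grid, sensor_pos, var = 1L, threshold,
                          direction = "down") {
  cond <- condition_threshold(grid, sensor_pos, var, threshold, direction)
  act <- function(sim, t) {
    s2t <- s2
    s2t$t_on <- t + s2$t_on
    s2t$t_off <- t + s2$t_off
    sim_add_stimulus(sim, s2t)
  }
  source_spec(stimuli = list(s1),
              triggers = list(trigger(cond, act, one_shot = TRUE)))
}
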