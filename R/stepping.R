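#' Explicit time stepping
#'
#' One-step advancement of the state by forward Euler or the classic
#' fourth-order Runge-Kutta scheme (weights 1/6, 1/3, 1/3, 1/6 with
#' half-step inner stages). The right-hand side `rhs(state, t)` combines the
#' projected diffusion term, the reaction term and any additive stimuli;
#' [euler_step()] evaluates it once per step, [rk4_step()] exactly four
#' times. The scheme can be selected per state variable via the model's
#' stepping tags; within a mixed step the RK4 inner stages hold
#' euler-tagged variables at their step-start values (the two schemes are
#' only coupled through the shared right-hand side, which is exact for
#' decoupled systems).
#'
#' @param rhs function `(state, t) -> d(state)/dt`, same shape as `state`.
#' @param state numeric vector, matrix or array.
#' @param t current time, ms.
#' @param dt time step, ms (> 0).
#' @return the state at `t + dt`.
#' @name time_stepping
NULL

#' @rdname time_stepping
#' @export
euler_step <- function(rhs, state, t, dt) {
  if (dt <= 0) stop_validation("dt must be > 0")
  state + dt * rhs(state, t)
}

#' @rdname time_stepping
#' @export
rk4_step <- function(rhs, state, t, dt) {
  if (dt <= 0) stop_validation("dt must be > 0")
  k1 <- rhs(state, t)
  k2 <- rhs(state + (dt / 2) * k1, t + dt / 2)
  k3 <- rhs(state + (dt / 2) * k2, t + dt / 2)
  k4 <- rhs(state + dt * k3, t + dt)
  state + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance a state matrix with per-variable scheme selection
#'
#' @param steppings character vector of `"euler"` / `"rk4"` tags, one per
#'   state variable (column of `state`).
#' @param state n x M state matrix.
#' @inheritParams time_stepping
#' @export
advance <- function(steppings, rhs, state, t, dt) {
  if (!all(steppings %in% c("euler", "rk4")))
    stop_validation("stepping tags must be 'euler' or 'rk4'")
  if (all(steppings == "euler")) return(euler_step(rhs, state, t, dt))
  if (all(steppings == "rk4")) return(rk4_step(rhs, state, t, dt))
  eul <- which(steppings == "euler")
  hold <- function(U0, U) { U[, eul] <- U0[, eul]; U }
  k1 <- rhs(state, t)
  k2 <- rhs(hold(state, state + (dt / 2) * k1), t + dt / 2)
  k3 <- rhs(hold(state, state + (dt / 2) * k2), t + dt / 2)
  k4 <- rhs(hold(state, state + dt * k3), t + dt)
  out <- state + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  out[, eul] <- state[, eul] + dt * k1[, eul]
  out
}
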