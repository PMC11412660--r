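#' Excitable-media cell models
#'
#' A cell model supplies the reaction term `r(u)` of the monodomain
#' reaction-diffusion equation, together with the projection diagonal `P`
#' (which state variables diffuse), the resting state, per-variable time
#' stepping tags, default parameters, and metadata (literature citation,
#' invariant state box, default tip-detection isovalues).
#'
#' The reaction function is vectorized over vertices: it maps an
#' `n x M` state matrix to an `n x M` matrix of time derivatives
#' (model units per ms).
#'
#' @name cell_models
NULL

new_cell_model <- function(name, var_names, rest, P, reaction, params,
                           steppings = NULL, metadata = list(),
                           rest_tol = 1e-8, box = NULL, box_start = NULL,
                           tip_vars = c(1L, 2L), tip_iso = NULL) {
  M <- length(var_names)
  if (is.null(steppings)) steppings <- rep("euler", M)
  stopifnot(length(rest) == M, length(P) == M, length(steppings) == M)
  structure(
    list(name = name, M = M, var_names = var_names, rest = as.numeric(rest),
         P = as.numeric(P), steppings = steppings, params = params,
         reaction_fn = reaction, metadata = metadata, rest_tol = rest_tol,
         box = box, box_start = if (is.null(box_start)) box else box_start,
         tip_vars = tip_vars, tip_iso = tip_iso, post_step = NULL,
         inner = NULL),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %s: %d variables (%s), P = diag(%s)\n", x$name,
              x$M, paste(x$var_names, collapse = ", "),
              paste(format(x$P), collapse = ", ")))
  invisible(x)
}

#' Evaluate the reaction term
#'
#' @param model a `cell_model`.
#' @param u state: numeric vector of length M, or an n x M matrix
#'   (rows = vertices).
#' @param t time, ms (models shipped here are autonomous; wrappers and
#'   multi-models may use it).
#' @param ctx evaluation context (used by multi-model dispatch: `$labels`).
#' @return du/dt with the shape of `u`, in model units per ms.
#' @export
reaction <- function(model, u, t = 0, ctx = list()) {
  vec <- is.null(dim(u))
  U <- if (vec) matrix(u, nrow = 1L) else u
  if (ncol(U) != model$M)
    stop_validation(sprintf("state must have %d variables", model$M))
  R <- model$reaction_fn(U, t, ctx)
  if (vec) as.numeric(R) else R
}

#' Resting state of a model
#'
#' The declared resting vector; simulations initialize all interior vertices
#' to it.
#' @param model a `cell_model`.
#' @export
resting_state <- function(model) model$rest

heav <- function(x) (x >= 0) + 0

#' One-variable cubic bistable (Nagumo) model
#'
#' `r(u) = k u (1 - u)(u - a)`: the classical bistable nonlinearity with
#' stable rest at 0, excited state 1, and threshold `a`.
#' @param k reaction rate (1/ms), default 8.
#' @param a threshold, default 0.15.
#' @export
model_1varpoly <- function(k = 8, a = 0.15) {
  p <- list(k = k, a = a)
  new_cell_model(
    "1VarPoly", "u", rest = 0, P = 1,
    reaction = function(U, t, ctx) {
      u <- U[, 1]
      cbind(p$k * u * (1 - u) * (u - p$a))
    },
    params = p,
    metadata = list(citation = "Nagumo bistable cubic (FitzHugh-Nagumo front limit)"),
    box = rbind(u = c(0, 1)),
    tip_vars = 1L, tip_iso = 0.5
  )
}

#' Aliev-Panfilov two-variable model (continuous epsilon)
#'
#' Phenomenological ventricular model with normalized voltage `u` in \[0, 1\]
#' and recovery variable `v`; time is in the model's native units (treated
#' as ms here). Only `u` diffuses.
#' @param k,a,eps0,mu1,mu2 model parameters (Aliev & Panfilov 1996 defaults).
#' @export
model_ap <- function(k = 8, a = 0.15, eps0 = 0.002, mu1 = 0.2, mu2 = 0.3) {
  p <- list(k = k, a = a, eps0 = eps0, mu1 = mu1, mu2 = mu2)
  new_cell_model(
    "AP", c("u", "v"), rest = c(0, 0), P = c(1, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; v <- U[, 2]
      eps <- p$eps0 + p$mu1 * v / (u + p$mu2)
      cbind(-p$k * u * (u - p$a) * (u - 1) - u * v,
            eps * (-v - p$k * u * (u - p$a - 1)))
    },
    params = p,
    metadata = list(citation = "Aliev & Panfilov, Chaos Solitons Fractals 7:293 (1996)"),
    box = rbind(u = c(0, 1), v = c(0, 2.7)),
    tip_iso = c(0.5, 0.75)
  )
}

#' Barkley model
#'
#' Fast-slow excitable model widely used for spiral-wave studies.
#' @param a,b,eps Barkley parameters (defaults a = 0.75, b = 0.02,
#'   eps = 0.02).
#' @export
model_ba <- function(a = 0.75, b = 0.02, eps = 0.02) {
  p <- list(a = a, b = b, eps = eps)
  new_cell_model(
    "Ba", c("u", "v"), rest = c(0, 0), P = c(1, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; v <- U[, 2]
      cbind(u * (1 - u) * (u - (v + p$b) / p$a) / p$eps,
            u - v)
    },
    params = p,
    metadata = list(citation = "Barkley, Physica D 49:61 (1991)"),
    box = rbind(u = c(0, 1), v = c(0, 1)),
    tip_iso = c(0.5, 0.5)
  )
}

#' FitzHugh-Nagumo model (variant a)
#'
#' The classical cubic FitzHugh-Nagumo oscillator/excitable system
#' `du = u - u^3/3 - v`, `dv = eps (u + beta - gamma v)`. The resting state
#' is computed numerically at construction.
#' @param eps,beta,gamma parameters (defaults 0.08, 0.7, 0.8).
#' @export
model_fhna <- function(eps = 0.08, beta = 0.7, gamma = 0.8) {
  p <- list(eps = eps, beta = beta, gamma = gamma)
  # rest: u - u^3/3 = (u + beta)/gamma
  f <- function(u) u - u^3 / 3 - (u + p$beta) / p$gamma
  ur <- stats::uniroot(f, c(-3, 3), tol = 1e-14)$root
  vr <- (ur + p$beta) / p$gamma
  new_cell_model(
    "FHNa", c("u", "v"), rest = c(ur, vr), P = c(1, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; v <- U[, 2]
      cbind(u - u^3 / 3 - v,
            p$eps * (u + p$beta - p$gamma * v))
    },
    params = p, rest_tol = 1e-10,
    metadata = list(citation = "FitzHugh, Biophys J 1:445 (1961); Nagumo et al., Proc IRE 50:2061 (1962)"),
    box = rbind(u = c(-3, 3), v = c(-2.875, 4.625)),
    tip_iso = c(0, 0)
  )
}

#' Mitchell-Schaeffer two-variable model
#'
#' Minimal ionic-style model with voltage `u` and gating variable `h`;
#' resting state (0, 1). Only `u` diffuses. Note the gate dynamics switch
#' discontinuously at `u_gate`.
#' @param tau_in,tau_out,tau_open,tau_close,u_gate parameters
#'   (Mitchell & Schaeffer 2003 defaults).
#' @export
model_ms <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                     tau_close = 150, u_gate = 0.13) {
  p <- list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
            tau_close = tau_close, u_gate = u_gate)
  new_cell_model(
    "MS", c("u", "h"), rest = c(0, 1), P = c(1, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; h <- U[, 2]
      open <- u < p$u_gate
      cbind(h * u * u * (1 - u) / p$tau_in - u / p$tau_out,
            ifelse(open, (1 - h) / p$tau_open, -h / p$tau_close))
    },
    params = p,
    metadata = list(citation = "Mitchell & Schaeffer, Bull Math Biol 65:767 (2003)"),
    box = rbind(u = c(0, 1), h = c(0, 1)),
    tip_iso = c(0.3, 0.5)
  )
}

#' Fenton-Karma three-variable model
#'
#' Three-current phenomenological model (fast inward, slow outward, slow
#' inward) with gates `v` and `w`; normalized voltage `u`. Defaults are the
#' Beeler-Reuter-derived parameter set of the original publication. Resting
#' state (0, 1, 1); only `u` diffuses. Because the slow inward current can
#' transiently push `u` above the plateau while `w` is still high, the
#' declared hold box is slightly larger in `u` than the start box.
#' @param params named list overriding any of the default parameters.
#' @export
model_fk <- function(params = list()) {
  p <- utils::modifyList(list(
    tau_d = 0.25, tau_r = 33, tau_si = 30, tau_0 = 12.5,
    tau_vp = 3.33, tau_vm1 = 1250, tau_vm2 = 19.6,
    tau_wp = 870, tau_wm = 41,
    u_c = 0.13, u_v = 0.04, u_csi = 0.85, k = 10), params)
  new_cell_model(
    "FK", c("u", "v", "w"), rest = c(0, 1, 1), P = c(1, 0, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; v <- U[, 2]; w <- U[, 3]
      exc <- heav(u - p$u_c)           # 1 above the excitation threshold
      J_fi <- -v / p$tau_d * exc * (1 - u) * (u - p$u_c)
      J_so <- u / p$tau_0 * (1 - exc) + exc / p$tau_r
      J_si <- -w / (2 * p$tau_si) * (1 + tanh(p$k * (u - p$u_csi)))
      tau_vm <- heav(u - p$u_v) * p$tau_vm1 + heav(p$u_v - u) * p$tau_vm2
      cbind(-(J_fi + J_so + J_si),
            (1 - exc) * (1 - v) / tau_vm - exc * v / p$tau_vp,
            (1 - exc) * (1 - w) / p$tau_wm - exc * w / p$tau_wp)
    },
    params = p,
    metadata = list(citation = "Fenton & Karma, Chaos 8:20 (1998), BR set"),
    box = rbind(u = c(0, 1.4), v = c(0, 1), w = c(0, 1)),
    box_start = rbind(u = c(0, 1.1), v = c(0, 1), w = c(0, 1)),
    tip_iso = c(0.5, 0.5)
  )
}

#' Bueno-Orovio minimal four-variable ventricular model
#'
#' The minimal human ventricular model with voltage `u` and gates `v`, `w`,
#' `s`. Default parameters are the epicardial (EPI) set. Resting state
#' (0, 1, 1, 0); only `u` diffuses.
#' @param params named list overriding any of the EPI defaults.
#' @export
model_bo <- function(params = list()) {
  p <- utils::modifyList(list(
    u_o = 0, u_u = 1.55, th_v = 0.3, th_w = 0.13, th_vm = 0.006,
    th_o = 0.006, tau_v1m = 60, tau_v2m = 1150, tau_vp = 1.4506,
    tau_w1m = 60, tau_w2m = 15, k_wm = 65, u_wm = 0.03, tau_wp = 200,
    tau_fi = 0.11, tau_o1 = 400, tau_o2 = 6, tau_so1 = 30.0181,
    tau_so2 = 0.9957, k_so = 2.0458, u_so = 0.65, tau_s1 = 2.7342,
    tau_s2 = 16, k_s = 2.0994, u_s = 0.9087, tau_si = 1.8875,
    tau_winf = 0.07, w_infstar = 0.94), params)
  # resting s is its quasi-steady value at u = 0 (the slow inward current
  # is gated off there, so this is an exact fixed point)
  s_rest <- (1 + tanh(p$k_s * (0 - p$u_s))) / 2
  new_cell_model(
    "BO", c("u", "v", "w", "s"), rest = c(0, 1, 1, s_rest),
    P = c(1, 0, 0, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; v <- U[, 2]; w <- U[, 3]; s <- U[, 4]
      Hv <- heav(u - p$th_v); Hw <- heav(u - p$th_w)
      Hvm <- heav(u - p$th_vm); Ho <- heav(u - p$th_o)
      tau_vm <- (1 - Hvm) * p$tau_v1m + Hvm * p$tau_v2m
      tau_wm <- p$tau_w1m +
        (p$tau_w2m - p$tau_w1m) * (1 + tanh(p$k_wm * (u - p$u_wm))) / 2
      tau_so <- p$tau_so1 +
        (p$tau_so2 - p$tau_so1) * (1 + tanh(p$k_so * (u - p$u_so))) / 2
      tau_s <- (1 - Hw) * p$tau_s1 + Hw * p$tau_s2
      tau_o <- (1 - Ho) * p$tau_o1 + Ho * p$tau_o2
      v_inf <- (u < p$th_vm) + 0
      w_inf <- (1 - Ho) * (1 - u / p$tau_winf) + Ho * p$w_infstar
      J_fi <- -v * Hv * (u - p$th_v) * (p$u_u - u) / p$tau_fi
      J_so <- (u - p$u_o) * (1 - Hw) / tau_o + Hw / tau_so
      J_si <- -Hw * w * s / p$tau_si
      cbind(-(J_fi + J_so + J_si),
            (1 - Hv) * (v_inf - v) / tau_vm - Hv * v / p$tau_vp,
            (1 - Hw) * (w_inf - w) / tau_wm - Hw * w / p$tau_wp,
            ((1 + tanh(p$k_s * (u - p$u_s))) / 2 - s) / tau_s)
    },
    params = p,
    metadata = list(citation = "Bueno-Orovio, Cherry & Fenton, J Theor Biol 253:544 (2008), EPI set"),
    box = rbind(u = c(0, 1.6), v = c(0, 1), w = c(0, 1), s = c(0, 1)),
    tip_iso = c(0.5, 0.5)
  )
}

#' Smooth Karma two-variable model
#'
#' Smoothed variant of the Karma model: voltage `u` with a smooth excitation
#' nonlinearity and slow recovery `v` with a smooth step activation,
#' `du = (-u + (u* - v^M) h(u)) / tau_u`, `h(u) = (1 - tanh(u - u_h)) u^2/2`,
#' `dv = (S(u - u_n) - v) / tau_v`, `S(x) = (1 + tanh(k x))/2`. The resting
#' state `(0, S(-u_n))` is computed at construction.
#' @param u_star,u_h,u_n,M,tau_u,tau_v,k_smooth parameters; the smooth-step
#'   steepness `k_smooth = 4` keeps the rest close to (0, 0).
#' @export
model_smooka <- function(u_star = 1.5415, u_h = 3, u_n = 1, M = 4,
                         tau_u = 2.5, tau_v = 250, k_smooth = 4) {
  p <- list(u_star = u_star, u_h = u_h, u_n = u_n, M = M,
            tau_u = tau_u, tau_v = tau_v, k_smooth = k_smooth)
  v_rest <- (1 + tanh(p$k_smooth * (0 - p$u_n))) / 2
  new_cell_model(
    "SmooKa", c("u", "v"), rest = c(0, v_rest), P = c(1, 0),
    reaction = function(U, t, ctx) {
      u <- U[, 1]; v <- U[, 2]
      h <- (1 - tanh(u - p$u_h)) * u * u / 2
      cbind((-u + (p$u_star - v^p$M) * h) / p$tau_u,
            ((1 + tanh(p$k_smooth * (u - p$u_n))) / 2 - v) / p$tau_v)
    },
    params = p,
    metadata = list(citation = "Karma, PRL 71:1103 (1993); smooth variant per Marcotte & Grigoriev, Chaos 27:093936 (2017)"),
    box = rbind(u = c(0, 4), v = c(0, 1)),
    tip_iso = c(1.5, 0.5)
  )
}

#' Shipped model menu
#'
#' @return named list of constructors for the shipped cell models.
#' @export
model_menu <- function() {
  list("1VarPoly" = model_1varpoly, "AP" = model_ap, "Ba" = model_ba,
       "FHNa" = model_fhna, "MS" = model_ms, "FK" = model_fk,
       "BO" = model_bo, "SmooKa" = model_smooka)
}

#' Construct a shipped model by name
#'
#' @param name model name as listed by [model_menu()].
#' @param ... passed to the model constructor (parameter overrides).
#' @export
make_model <- function(name, ...) {
  menu <- model_menu()
  if (!name %in% names(menu))
    stop_validation(sprintf("unknown model '%s'; available: %s", name,
                            paste(names(menu), collapse = ", ")))
  menu[[name]](...)
}
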