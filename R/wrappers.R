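#' Model wrappers
#'
#' Wrappers extend a cell model with additional recording variables that are
#' updated by side effect at the end of every time step: the diffusion or
#' reaction term of selected variables, or local activation/deactivation
#' times (LAT/LDT). Added variables never diffuse (projection entry 0) and
#' contribute zero to the reaction term; the simulation engine drives their
#' updates through the wrapper's post-step hook. Wrappers compose: each adds
#' its variables after all of the wrapped model's, and chains the inner
#' post-step hook before its own.
#'
#' @name model_wrappers
NULL

new_wrapper <- function(model, add_names, add_rest, post_step,
                        name_suffix, extra = list()) {
  Mi <- model$M
  out <- new_cell_model(
    name = paste0(model$name, "+", name_suffix),
    var_names = c(model$var_names, add_names),
    rest = c(model$rest, add_rest),
    P = c(model$P, rep(0, length(add_names))),
    reaction = NULL,
    params = model$params,
    steppings = c(model$steppings, rep("euler", length(add_names))),
    metadata = model$metadata,
    rest_tol = model$rest_tol,
    box = model$box, box_start = model$box_start,
    tip_vars = model$tip_vars, tip_iso = model$tip_iso
  )
  out$inner <- model
  out$reaction_fn <- function(U, t, ctx) {
    Ri <- model$reaction_fn(U[, seq_len(Mi), drop = FALSE], t, ctx)
    cbind(Ri, matrix(0, nrow(U), length(add_names)))
  }
  inner_hook <- model$post_step
  out$post_step <- function(Unew, Uold, t0, dt, ctx) {
    if (!is.null(inner_hook)) Unew <- inner_hook(Unew, Uold, t0, dt, ctx)
    post_step(Unew, Uold, t0, dt, ctx)
  }
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Record the diffusion term of selected variables
#'
#' Adds one variable per selected index holding the current discrete
#' `div(D grad u)` of that variable (unscaled by the projection matrix),
#' updated every step. Required input of the pseudo-electrogram computation.
#'
#' @param model a `cell_model`.
#' @param which variable indices whose diffusion term to record.
#' @return a wrapped `cell_model`; the added variables are named
#'   `diff_<var>` and start at 0.
#' @export
wrap_record_diffusion <- function(model, which = 1L) {
  which <- as.integer(which)
  if (any(which < 1L) || any(which > model$M))
    stop_validation("recorded variable index out of range")
  Mi <- model$M
  cols <- Mi + seq_along(which)
  new_wrapper(
    model,
    add_names = paste0("diff_", model$var_names[which]),
    add_rest = rep(0, length(which)),
    post_step = function(Unew, Uold, t0, dt, ctx) {
      for (j in seq_along(which))
        Unew[, cols[j]] <- ctx$diffusion_of(Unew[, which[j]])
      Unew
    },
    name_suffix = "RecDiff",
    extra = list(recorded_diffusion = stats::setNames(cols, which))
  )
}

#' Record the reaction term of selected variables
#'
#' Adds one variable per selected index holding the wrapped model's reaction
#' term evaluated at the current state.
#' @inheritParams wrap_record_diffusion
#' @export
wrap_record_reaction <- function(model, which = 1L) {
  which <- as.integer(which)
  if (any(which < 1L) || any(which > model$M))
    stop_validation("recorded variable index out of range")
  Mi <- model$M
  cols <- Mi + seq_along(which)
  new_wrapper(
    model,
    add_names = paste0("react_", model$var_names[which]),
    add_rest = rep(0, length(which)),
    post_step = function(Unew, Uold, t0, dt, ctx) {
      R <- model$reaction_fn(Unew[, seq_len(Mi), drop = FALSE], t0 + dt, ctx)
      for (j in seq_along(which)) Unew[, cols[j]] <- R[, which[j]]
      Unew
    },
    name_suffix = "RecReact"
  )
}

#' Record local activation / deactivation times
#'
#' Adds a variable holding the time of the most recent threshold crossing of
#' the monitored variable: upward crossings for LAT, downward for LDT. The
#' crossing time within a step is linearly interpolated. Vertices that never
#' cross hold the sentinel (-1 ms, "never activated"; all stimuli are at
#' t >= 0).
#'
#' @param model a `cell_model`.
#' @param var index of the monitored variable.
#' @param threshold crossing threshold, in the variable's units.
#' @param direction `"up"` (LAT) or `"down"` (LDT).
#' @param sentinel value marking "never crossed" (default -1).
#' @export
wrap_record_lat <- function(model, var = 1L, threshold,
                            direction = c("up", "down"), sentinel = -1) {
  direction <- match.arg(direction)
  var <- as.integer(var)
  if (var < 1L || var > model$M)
    stop_validation("monitored variable index out of range")
  col <- model$M + 1L
  nm <- paste0(if (direction == "up") "lat_" else "ldt_",
               model$var_names[var])
  new_wrapper(
    model,
    add_names = nm,
    add_rest = sentinel,
    post_step = function(Unew, Uold, t0, dt, ctx) {
      uo <- Uold[, var]; un <- Unew[, var]
      hit <- if (direction == "up") uo < threshold & un >= threshold
             else uo > threshold & un <= threshold
      if (any(hit)) {
        frac <- (threshold - uo[hit]) / (un[hit] - uo[hit])
        Unew[hit, col] <- t0 + dt * frac
      }
      Unew
    },
    name_suffix = if (direction == "up") "LAT" else "LDT",
    extra = list(lat_col = col, lat_sentinel = sentinel)
  )
}

#' @rdname wrap_record_lat
#' @export
wrap_record_ldt <- function(model, var = 1L, threshold, sentinel = -1) {
  wrap_record_lat(model, var, threshold, direction = "down",
                  sentinel = sentinel)
}

#' Linearly rescale a model in time, space, and variable units
#'
#' Reaction outputs are scaled by `1/time_factor` (slowing the model down by
#' `time_factor`); the spatial rescaling does not alter the reaction term
#' but changes the diffusivity a user should pair with the model by
#' `space_factor^2 / time_factor` (stored in the metadata). Per-variable
#' affine maps `u_outer = scale * u_inner + shift` convert between model
#' units and user units (e.g. a 0..1 normalized voltage to mV).
#'
#' @param model a `cell_model`.
#' @param time_factor,space_factor positive scalars.
#' @param var_scale,var_shift numeric vectors of length M (defaults: 1, 0).
#' @export
rescale_model <- function(model, time_factor = 1, space_factor = 1,
                          var_scale = NULL, var_shift = NULL) {
  if (time_factor <= 0 || space_factor <= 0)
    stop_validation("rescaling factors must be > 0")
  M <- model$M
  a <- if (is.null(var_scale)) rep(1, M) else rep_len(var_scale, M)
  b <- if (is.null(var_shift)) rep(0, M) else rep_len(var_shift, M)
  if (any(a == 0)) stop_validation("variable scale factors must be nonzero")
  to_inner <- function(U) sweep(sweep(U, 2, b, `-`), 2, a, `/`)
  out <- new_cell_model(
    name = paste0(model$name, "+Rescale"),
    var_names = model$var_names,
    rest = a * model$rest + b,
    P = model$P,
    reaction = NULL,
    params = model$params,
    steppings = model$steppings,
    metadata = c(model$metadata,
                 list(diffusivity_scale = space_factor^2 / time_factor)),
    rest_tol = model$rest_tol * max(abs(a)),
    box = if (!is.null(model$box)) model$box * a + b,
    box_start = if (!is.null(model$box_start)) model$box_start * a + b,
    tip_vars = model$tip_vars,
    tip_iso = if (!is.null(model$tip_iso))
      model$tip_iso * a[model$tip_vars] + b[model$tip_vars]
  )
  out$inner <- model
  out$reaction_fn <- function(U, t, ctx) {
    R <- model$reaction_fn(to_inner(U), t / time_factor, ctx)
    sweep(R, 2, a / time_factor, `*`)
  }
  inner_hook <- model$post_step
  if (!is.null(inner_hook)) {
    out$post_step <- function(Unew, Uold, t0, dt, ctx) {
      Ui <- inner_hook(to_inner(Unew), to_inner(Uold),
                       t0 / time_factor, dt / time_factor, ctx)
      sweep(sweep(Ui, 2, a, `*`), 2, b, `+`)
    }
  }
  out
}

#' Combine submodels into one spatially dispatched model
#'
#' The reaction term at each vertex is taken from the submodel selected by
#' the vertex's inhom label (label n uses the n-th submodel; label 0 is
#' exterior and never evaluated). Submodels with fewer variables are padded
#' with inert zero-dynamics variables to the largest M. All submodels must
#' agree on the projection diagonal and stepping tags of their shared
#' variables.
#'
#' @param models list of `cell_model`s.
#' @param inhom an [inhom_field()] whose labels the combined model must
#'   cover (max label <= number of submodels).
#' @return a `cell_model` whose reaction dispatches on `ctx$labels`.
#' @export
multi_model <- function(models, inhom = NULL) {
  if (!length(models) || !all(vapply(models, inherits, TRUE, "cell_model")))
    stop_validation("models must be a non-empty list of cell_model objects")
  if (!is.null(inhom)) {
    if (max(inhom) > length(models))
      stop_validation("inhom label exceeds the number of submodels")
  }
  M <- max(vapply(models, function(m) m$M, 1L))
  pad <- function(m) {
    if (m$M == M) return(m)
    k <- M - m$M
    p <- m
    p$var_names <- c(m$var_names, paste0("pad", seq_len(k)))
    p$rest <- c(m$rest, rep(0, k))
    p$P <- c(m$P, rep(0, k))
    p$steppings <- c(m$steppings, rep("euler", k))
    p$M <- M
    inner_fn <- m$reaction_fn
    p$reaction_fn <- function(U, t, ctx) {
      cbind(inner_fn(U[, seq_len(m$M), drop = FALSE], t, ctx),
            matrix(0, nrow(U), k))
    }
    p
  }
  subs <- lapply(models, pad)
  P <- subs[[1]]$P
  for (s in subs) if (!identical(s$P, P))
    stop_validation("submodels must agree on the projection diagonal")
  if (any(vapply(subs, function(s) !is.null(s$post_step), TRUE)))
    stop_validation("wrap recording wrappers around the multi-model, not inside it")
  out <- new_cell_model(
    name = paste0("Multi(", paste(vapply(models, function(m) m$name, ""),
                                  collapse = ", "), ")"),
    var_names = subs[[1]]$var_names,
    rest = subs[[1]]$rest,
    P = P,
    reaction = function(U, t, ctx) {
      labels <- ctx$labels
      if (is.null(labels))
        stop_validation("multi-model evaluation requires ctx$labels")
      R <- matrix(0, nrow(U), M)
      for (k in seq_along(subs)) {
        rows <- which(labels == k)
        if (length(rows))
          R[rows, ] <- subs[[k]]$reaction_fn(U[rows, , drop = FALSE], t, ctx)
      }
      R
    },
    params = list(),
    steppings = subs[[1]]$steppings,
    metadata = list(submodels = lapply(models, function(m) m$name)),
    box = subs[[1]]$box, box_start = subs[[1]]$box_start,
    tip_vars = subs[[1]]$tip_vars, tip_iso = subs[[1]]$tip_iso
  )
  out$submodels <- subs
  out$is_multi <- TRUE
  out
}

# per-vertex resting state; multi-models rest each region at its own
# submodel's resting vector (exterior rows get submodel 1's rest)
resting_matrix <- function(model, labels) {
  n <- length(labels)
  if (isTRUE(model$is_multi)) {
    U <- matrix(rep(model$submodels[[1]]$rest, each = n), n, model$M)
    for (k in seq_along(model$submodels)) {
      rows <- which(labels == k)
      if (length(rows))
        U[rows, ] <- matrix(rep(model$submodels[[k]]$rest, each = length(rows)),
                            length(rows), model$M)
    }
    U
  } else {
    matrix(rep(model$rest, each = n), n, model$M)
  }
}
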