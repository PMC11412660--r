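#' Discretized simulation grid
#'
#' Defines a node-centered N-dimensional box grid on which all fields live.
#' Vertex positions along axis `n` are `origin[n] + (index - 1) * spacing[n]`
#' (indices are 1-based in R; the first vertex sits at the origin).
#'
#' @param shape integer vector, number of vertices per axis (all >= 1).
#' @param spacing numeric vector, grid spacing per axis in mm (all > 0).
#'   Recycled to `length(shape)` if scalar.
#' @param origin numeric vector, position of the first vertex in mm
#'   (default 0 on every axis).
#' @return An object of class `grid_spec` with fields `shape`, `spacing`,
#'   `origin`, `N` (number of axes) and `n` (total vertex count).
#' @examples
#' g <- grid_spec(c(30, 30), spacing = 1)
#' g$n  # 900 vertices
#' @export
grid_spec <- function(shape, spacing, origin = 0) {
  shape <- as.integer(shape)
  if (length(shape) < 1L || any(shape < 1L))
    stop_validation("grid shape must have >= 1 vertex per axis")
  N <- length(shape)
  spacing <- rep_len(as.numeric(spacing), N)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_validation("grid spacing must be positive and finite")
  origin <- rep_len(as.numeric(origin), N)
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         N = N, n = prod(shape)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s vertices, spacing (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

# 1-based vertex index matrix (n x N), x fastest (R column-major order).
grid_indices <- function(grid) {
  arrayInd(seq_len(grid$n), .dim = grid$shape)
}

#' Vertex positions in mm
#'
#' @param grid a [grid_spec()].
#' @return n x N matrix of vertex positions (mm), rows in linear vertex order
#'   (x fastest).
#' @export
grid_positions <- function(grid) {
  idx <- grid_indices(grid)
  pos <- sweep(idx - 1L, 2L, grid$spacing, `*`)
  sweep(pos, 2L, grid$origin, `+`)
}

# linear index from 1-based per-axis indices (matrix rows), NA when out of bounds
grid_linear_index <- function(grid, idx) {
  sh <- grid$shape
  ok <- rep(TRUE, nrow(idx))
  for (a in seq_len(grid$N)) ok <- ok & idx[, a] >= 1L & idx[, a] <= sh[a]
  lin <- rep(NA_integer_, nrow(idx))
  if (any(ok)) {
    sub <- idx[ok, , drop = FALSE]
    l <- sub[, 1]
    mult <- 1
    for (a in seq_len(grid$N)[-1]) {
      mult <- mult * sh[a - 1]
      l <- l + (sub[, a] - 1L) * mult
    }
    lin[ok] <- as.integer(l)
  }
  lin
}

# nearest vertex (linear index) to a position in mm
grid_nearest_vertex <- function(grid, pos) {
  pos <- as.numeric(pos)
  if (length(pos) != grid$N)
    stop_validation("position dimensionality does not match the grid")
  idx <- round((pos - grid$origin) / grid$spacing) + 1
  idx <- pmin(pmax(as.integer(idx), 1L), grid$shape)
  grid_linear_index(grid, matrix(idx, nrow = 1L))
}

#' Inhomogeneity (tissue label) field
#'
#' Integer label per vertex: 0 marks exterior points (no dynamics, zero-flux
#' obstacle), n >= 1 marks interior points governed by submodel n of a
#' multi-model (or simply "tissue" for a single model).
#'
#' @param grid a [grid_spec()].
#' @param labels integer array of dimension `grid$shape` (or a scalar,
#'   recycled). Default: all vertices interior with label 1.
#' @return integer array of class `inhom_field` with the grid attached.
#' @export
inhom_field <- function(grid, labels = 1L) {
  if (length(labels) == 1L) labels <- array(labels, dim = grid$shape)
  if (is.null(dim(labels)) && grid$N == 1L) dim(labels) <- grid$shape
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop_validation("inhom labels must have the grid's shape")
  if (any(labels != round(labels)) || any(labels < 0))
    stop_validation("inhom labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(labels, class = "inhom_field", grid = grid)
}

as_inhom <- function(grid, inhom) {
  if (is.null(inhom)) inhom_field(grid) else {
    if (!inherits(inhom, "inhom_field")) inhom_field(grid, inhom) else inhom
  }
}

#' Local fiber frame of the medium
#'
#' Stores the local orthonormal frame of cardiac muscle: the fiber direction
#' `ef`, the sheet direction `es`, and (in 3D) their cross product. The frame
#' may be spatially constant (one row) or given per vertex (n rows).
#'
#' @param ef,es unit vectors: length-N numeric vectors for a constant frame,
#'   or n x N matrices for a per-vertex frame.
#' @param tol orthonormality tolerance (default 1e-6).
#' @return object of class `fiber_field`.
#' @export
fiber_field <- function(ef, es, tol = 1e-6) {
  if (is.null(dim(ef))) ef <- matrix(ef, nrow = 1L)
  if (is.null(dim(es))) es <- matrix(es, nrow = 1L)
  if (!identical(dim(ef), dim(es)))
    stop_validation("ef and es must have identical dimensions")
  nf <- sqrt(rowSums(ef^2)); ns <- sqrt(rowSums(es^2))
  dots <- rowSums(ef * es)
  if (any(abs(nf - 1) > tol) || any(abs(ns - 1) > tol) || any(abs(dots) > tol))
    stop_validation("fiber frame is not orthonormal (|e|=1, ef . es = 0)")
  structure(list(ef = ef, es = es, N = ncol(ef)), class = "fiber_field")
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Diffusivity specification
#'
#' Either a single scalar diffusivity (isotropic medium) or three
#' diffusivities along the fiber, sheet, and sheet-normal directions
#' (orthotropic medium) together with a [fiber_field()].
#'
#' @param D scalar isotropic diffusivity, mm^2/ms.
#' @param Df,Ds,Dx diffusivities along fiber / sheet / cross directions,
#'   mm^2/ms (all >= 0).
#' @param fibers a [fiber_field()] (required for the orthotropic form).
#' @return object of class `diffusion_spec`.
#' @export
diffusion_iso <- function(D) {
  D <- as.numeric(D)
  if (length(D) != 1L || !is.finite(D) || D < 0)
    stop_validation("isotropic diffusivity must be a single value >= 0")
  structure(list(type = "iso", D = D), class = "diffusion_spec")
}

#' @rdname diffusion_iso
#' @export
diffusion_aniso <- function(Df, Ds, Dx = Ds, fibers) {
  d <- c(Df, Ds, Dx)
  if (any(!is.finite(d)) || any(d < 0))
    stop_validation("diffusivities must be >= 0")
  if (!inherits(fibers, "fiber_field"))
    stop_validation("anisotropic diffusion requires a fiber_field")
  structure(list(type = "aniso", Df = Df, Ds = Ds, Dx = Dx, fibers = fibers),
            class = "diffusion_spec")
}

#' Build the diffusion tensor field from fibers and diffusivities
#'
#' Computes `D = Df ef ef' + Ds es es' + Dx ex ex'` at every vertex, where
#' `ex = ef x es` (3D; in 2D only the fiber and sheet terms contribute).
#'
#' @param fibers a [fiber_field()].
#' @param spec an anisotropic [diffusion_aniso()] specification (its own
#'   `fibers` entry is ignored in favor of `fibers`).
#' @return a `tensor_field`: array of dimension (rows, N, N), symmetric
#'   positive semidefinite at every row; one row if the frame is constant.
#' @export
build_diffusion_tensor <- function(fibers, spec) {
  if (!inherits(fibers, "fiber_field"))
    stop_validation("fibers must be a fiber_field")
  if (!inherits(spec, "diffusion_spec") || spec$type != "aniso")
    stop_validation("spec must carry the anisotropic form (three diffusivities)")
  N <- fibers$N
  ef <- fibers$ef; es <- fibers$es
  nr <- nrow(ef)
  D <- array(0, dim = c(nr, N, N))
  add_outer <- function(D, d, e) {
    for (a in seq_len(N)) for (b in seq_len(N))
      D[, a, b] <- D[, a, b] + d * e[, a] * e[, b]
    D
  }
  D <- add_outer(D, spec$Df, ef)
  D <- add_outer(D, spec$Ds, es)
  if (N == 3L) D <- add_outer(D, spec$Dx, cross3(ef, es))
  structure(D, class = "tensor_field")
}

#' Constant diffusion tensor field
#'
#' Convenience constructor wrapping one symmetric N x N matrix as a
#' (spatially constant) `tensor_field`.
#' @param M symmetric positive semidefinite matrix, mm^2/ms.
#' @export
tensor_constant <- function(M) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-9)
    stop_validation("diffusion tensor must be symmetric")
  N <- nrow(M)
  structure(array(M, dim = c(1L, N, N)), class = "tensor_field")
}

# expand a tensor_field to one row per vertex; validate symmetry/PSD
tensor_rows <- function(tensor, grid) {
  d <- dim(tensor)
  if (length(d) != 3L || d[2] != d[3])
    stop_validation("tensor field must be an (rows, N, N) array")
  if (d[2] != grid$N)
    stop_validation("tensor dimensionality does not match the grid")
  if (d[1] == 1L) {
    out <- array(tensor[rep(1L, grid$n), , ], dim = c(grid$n, d[2], d[3]))
  } else if (d[1] == grid$n) {
    out <- unclass(tensor)
  } else stop_validation("tensor field rows must match the vertex count")
  check_tensor_psd(out)
  out
}

# symmetry + PSD via principal minors (N <= 3), vectorized over vertices
check_tensor_psd <- function(D, tol = 1e-9) {
  N <- dim(D)[2]
  for (a in seq_len(N)) for (b in seq_len(N)) if (a < b) {
    if (max(abs(D[, a, b] - D[, b, a])) > tol)
      stop_validation("diffusion tensor must be symmetric")
  }
  scale <- pmax(apply(abs(D), 1, max), 1)
  for (a in seq_len(N))
    if (any(D[, a, a] < -tol * scale))
      stop_validation("diffusion tensor must be positive semidefinite")
  if (N >= 2) {
    for (a in seq_len(N)) for (b in seq_len(N)) if (a < b) {
      m <- D[, a, a] * D[, b, b] - D[, a, b]^2
      if (any(m < -tol * scale^2))
        stop_validation("diffusion tensor must be positive semidefinite")
    }
  }
  if (N == 3) {
    det3 <- D[, 1, 1] * (D[, 2, 2] * D[, 3, 3] - D[, 2, 3]^2) -
      D[, 1, 2] * (D[, 1, 2] * D[, 3, 3] - D[, 2, 3] * D[, 1, 3]) +
      D[, 1, 3] * (D[, 1, 2] * D[, 2, 3] - D[, 2, 2] * D[, 1, 3])
    if (any(det3 < -tol * scale^3))
      stop_validation("diffusion tensor must be positive semidefinite")
  }
  invisible(TRUE)
}

stop_validation <- function(msg) {
  stop(structure(class = c("mw_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
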