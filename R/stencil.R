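#' Finite-difference diffusion stencils
#'
#' A stencil operator discretizes the divergence-form diffusion term
#' `div(D grad u)` on the grid as a sparse matrix acting on a flattened
#' state-variable layer. Zero-flux (Neumann) boundaries and obstacle
#' (exterior-vertex) exclusion are folded into the weights: the flux through
#' any face touching a non-interior vertex is zero, which makes the operator
#' exactly conservative (the plain sum of its output vanishes for any field)
#' and gives every row a zero weight sum. The diagonal is assembled as minus
#' the off-diagonal row sum, so constants are annihilated to rounding error.
#'
#' @name stencils
NULL

x_strides <- function(grid) cumprod(c(1, grid$shape))[seq_len(grid$N)]

# Finalize a stencil: any explicit diagonal terms (one-sided tangential
# differences produce them) are stripped and the diagonal is re-derived as
# minus the off-diagonal row sum, which the exact operator satisfies (every
# flux stencil annihilates constants).
new_stencil <- function(W_full, grid, interior, type) {
  d <- Matrix::diag(W_full)
  W_off <- W_full - Matrix::Diagonal(grid$n, d)
  rs <- Matrix::rowSums(W_off)
  W <- W_off + Matrix::Diagonal(grid$n, -rs)
  W <- methods::as(Matrix::drop0(W), "CsparseMatrix")
  structure(list(W = W, grid = grid, interior = interior, radius = 1L,
                 type = type),
            class = "stencil_op")
}

#' @export
print.stencil_op <- function(x, ...) {
  cat(sprintf("<stencil_op> %s, %d vertices (%d interior), %d nonzeros\n",
              x$type, x$grid$n, sum(x$interior), Matrix::nnzero(x$W)))
  invisible(x)
}

#' Isotropic diffusion stencil (2N+1 points)
#'
#' Nearest-neighbor Laplacian-type stencil: an interior vertex with all 2N
#' neighbors interior gets neighbor weights `D / dx_n^2` and center weight
#' minus their sum (5-point in 2D, 7-point in 3D). Faces to boundary or
#' exterior vertices carry zero flux.
#'
#' @param grid a [grid_spec()].
#' @param D scalar diffusivity, mm^2/ms (>= 0; 0 yields the zero operator).
#' @param P_max_entry largest diagonal entry of the projection matrix; only
#'   used to attach the stencil-weight CFL step bound (`$cfl_dt`).
#' @param inhom optional [inhom_field()]; default all interior.
#' @return a `stencil_op` with sparse matrix `$W` (1/ms units) and `$cfl_dt`.
#' @export
isotropic_stencil <- function(grid, D, P_max_entry = 1, inhom = NULL) {
  if (!is.finite(D) || D < 0) stop_validation("diffusivity D must be >= 0")
  inhom <- as_inhom(grid, inhom)
  interior <- as.vector(inhom) > 0L
  idx <- grid_indices(grid)
  st <- x_strides(grid)
  ii <- list(); jj <- list(); xx <- list(); k <- 0L
  for (a in seq_len(grid$N)) {
    w <- D / (grid$spacing[a] * grid$spacing[a])
    if (w == 0) next
    for (s in c(-1L, 1L)) {
      inb <- if (s > 0L) idx[, a] < grid$shape[a] else idx[, a] > 1L
      i <- which(interior & inb)
      j <- i + s * st[a]
      keep <- interior[j]
      i <- i[keep]; j <- j[keep]
      if (length(i)) {
        k <- k + 1L
        ii[[k]] <- i; jj[[k]] <- j; xx[[k]] <- rep.int(w, length(i))
      }
    }
  }
  if (k > 0L) {
    W_off <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                  x = unlist(xx), dims = c(grid$n, grid$n))
  } else {
    W_off <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(grid$n, grid$n))
  }
  op <- new_stencil(W_off, grid, interior, "isotropic")
  op$cfl_dt <- stencil_cfl(op, P_max_entry)
  op
}

#' Orthotropic diffusion stencil (9/19 points)
#'
#' Discretizes `div(D grad u)` for a full symmetric tensor field in
#' face-centered flux form: tensor entries are linearly interpolated to face
#' midpoints, the face-normal derivative is a two-point difference, and
#' in-face tangential derivatives (the mixed terms) are central differences
#' averaged over the two face endpoints, falling back to one-sided
#' differences where a needed vertex is exterior or outside the grid. The
#' footprint is the nearest plus in-plane diagonal neighbors: 9 points in 2D
#' and 19 in 3D. With a diagonal constant tensor the weights reduce exactly
#' to [isotropic_stencil()].
#'
#' @param grid a [grid_spec()].
#' @param tensor a `tensor_field` (one row, or one row per vertex).
#' @param P_max_entry see [isotropic_stencil()].
#' @param inhom optional [inhom_field()].
#' @return a `stencil_op`.
#' @export
orthotropic_stencil <- function(grid, tensor, P_max_entry = 1, inhom = NULL) {
  inhom <- as_inhom(grid, inhom)
  interior <- as.vector(inhom) > 0L
  D <- tensor_rows(tensor, grid)
  idx <- grid_indices(grid)
  st <- x_strides(grid)
  sh <- grid$shape
  dx <- grid$spacing
  n <- grid$n
  ii <- list(); jj <- list(); xx <- list(); k <- 0L
  emit <- function(r, c, v) {
    keep <- v != 0
    if (any(keep)) {
      k <<- k + 1L
      ii[[k]] <<- r[keep]; jj[[k]] <<- c[keep]; xx[[k]] <<- v[keep]
    }
  }
  # derivative of u along axis b at vertices v, as (column, coefficient)
  # pairs scaled by `scale`; emitted into rows `row`
  emit_tang <- function(row, v, b, scale) {
    hasp <- idx[v, b] < sh[b]
    hasp[hasp] <- interior[v[hasp] + st[b]]
    hasm <- idx[v, b] > 1L
    hasm[hasm] <- interior[v[hasm] - st[b]]
    ctr <- hasp & hasm
    if (any(ctr)) {
      c2 <- scale[ctr] / (2 * dx[b])
      emit(row[ctr], v[ctr] + st[b], c2)
      emit(row[ctr], v[ctr] - st[b], -c2)
    }
    po <- hasp & !hasm
    if (any(po)) {
      c1 <- scale[po] / dx[b]
      emit(row[po], v[po] + st[b], c1)
      emit(row[po], v[po], -c1)
    }
    mo <- hasm & !hasp
    if (any(mo)) {
      c1 <- scale[mo] / dx[b]
      emit(row[mo], v[mo], c1)
      emit(row[mo], v[mo] - st[b], -c1)
    }
  }
  for (a in seq_len(grid$N)) {
    i <- which(interior & idx[, a] < sh[a])
    j <- i + st[a]
    keep <- interior[j]
    i <- i[keep]; j <- j[keep]
    if (!length(i)) next
    # face-normal term: Daa at the face midpoint
    Daa <- 0.5 * (D[i, a, a] + D[j, a, a])
    cn <- Daa / (dx[a] * dx[a])
    emit(i, j, cn); emit(j, i, cn)
    emit(i, i, -cn); emit(j, j, -cn)
    # mixed terms: Dab * (tangential derivative interpolated to the face)
    for (b in seq_len(grid$N)) {
      if (b == a) next
      Dab <- 0.5 * (D[i, a, b] + D[j, a, b])
      if (all(Dab == 0)) next
      half <- 0.5 * Dab / dx[a]
      # average of the tangential derivative at the two face endpoints,
      # divergence: +F/dx_a into row i, -F/dx_a into row j
      emit_tang(i, i, b, half); emit_tang(i, j, b, half)
      emit_tang(j, i, b, -half); emit_tang(j, j, b, -half)
    }
  }
  if (length(ii)) {
    W_full <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                   x = unlist(xx), dims = c(n, n))
  } else {
    W_full <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(n, n))
  }
  op <- new_stencil(W_full, grid, interior, "orthotropic")
  op$cfl_dt <- stencil_cfl(op, P_max_entry)
  op
}

#' Apply a diffusion stencil to a state-variable layer
#'
#' @param stencil a `stencil_op`.
#' @param field numeric array of the grid's shape (or flat vector of length
#'   `grid$n`).
#' @return the discrete `div(D grad u)` estimate, same shape as `field`;
#'   exterior vertices are 0.
#' @export
apply_diffusion <- function(stencil, field) {
  v <- as.numeric(field)
  if (length(v) != stencil$grid$n)
    stop_validation("field shape does not match the stencil's grid")
  y <- as.numeric(stencil$W %*% v)
  if (!is.null(dim(field))) dim(y) <- dim(field)
  y
}

# largest stable dt from the assembled weights (Gershgorin bound)
stencil_cfl <- function(stencil, P_max_entry) {
  if (P_max_entry <= 0) return(Inf)
  A <- abs(stencil$W)
  off <- Matrix::rowSums(A) - abs(Matrix::diag(stencil$W))
  m <- max(off, 0)
  if (m == 0) Inf else 1 / (P_max_entry * m)
}

#' CFL time-step bound for explicit stepping
#'
#' Largest stable time step for the explicit diffusion update. For isotropic
#' or diagonal diffusion this is the classical bound
#' `[2 maxP sum_n Dnn / dx_n^2]^-1` (with `Dnn` the largest diagonal entry
#' over vertices). For full tensors, and for any pre-assembled stencil, the
#' conservative stencil-weight (Gershgorin) generalization
#' `[maxP max_i sum_j |w_ij|]^-1` over off-center weights is used.
#'
#' @param grid a [grid_spec()] (ignored when `diffusion` is a `stencil_op`).
#' @param diffusion a [diffusion_iso()]/[diffusion_aniso()] spec, a
#'   `tensor_field`, or a `stencil_op`.
#' @param P_max_entry largest diagonal entry of the projection matrix (> 0;
#'   a model in which no variable diffuses gives `Inf`).
#' @param inhom optional mask used when a stencil has to be assembled.
#' @return maximum stable dt in ms (`Inf` for the reaction-only system).
#' @export
cfl_bound <- function(grid, diffusion, P_max_entry = 1, inhom = NULL) {
  if (P_max_entry <= 0) return(Inf)
  if (inherits(diffusion, "stencil_op"))
    return(stencil_cfl(diffusion, P_max_entry))
  if (inherits(diffusion, "diffusion_spec")) {
    if (diffusion$type == "iso") {
      s <- sum(diffusion$D / grid$spacing^2)
      return(if (s == 0) Inf else 1 / (2 * P_max_entry * s))
    }
    diffusion <- build_diffusion_tensor(diffusion$fibers, diffusion)
  }
  if (inherits(diffusion, "tensor_field")) {
    D <- tensor_rows(diffusion, grid)
    offdiag <- 0
    for (a in seq_len(grid$N)) for (b in seq_len(grid$N))
      if (a != b) offdiag <- max(offdiag, max(abs(D[, a, b])))
    if (offdiag == 0) {
      s <- 0
      for (a in seq_len(grid$N)) s <- s + max(D[, a, a]) / grid$spacing[a]^2
      return(if (s == 0) Inf else 1 / (2 * P_max_entry * s))
    }
    op <- orthotropic_stencil(grid, diffusion, P_max_entry, inhom)
    return(op$cfl_dt)
  }
  stop_validation("diffusion must be a diffusion_spec, tensor_field or stencil_op")
}
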