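#' Pseudo-electrogram computation
#'
#' The extracellular potential at an electrode outside the tissue is
#' approximated in the pseudo-bidomain sense as a 1/r-kernel integral of
#' the diffusion term of the transmembrane voltage over the tissue:
#' `phi_e(x_e, t) = prefactor * sum_x voxel_volume * (div D grad u)(x, t)
#' / ||x_e - x||`, discretized by midpoint (voxel-sum) quadrature over the
#' interior vertices. The prefactor (`tau_e / 4 pi`, units ms) is fully
#' user-controlled. The diffusion term must be recorded during the run via
#' [wrap_record_diffusion()].
#'
#' @name electrogram
NULL

#' Electrode definition
#'
#' @param pos electrode position, mm. May carry more coordinates than the
#'   grid has axes (e.g. a z offset above a 2D sheet); missing grid
#'   coordinates are treated as 0.
#' @param prefactor scalar kernel prefactor (`tau_e / 4 pi`), ms.
#' @param lag sampling interval, ms (`NULL`: every step).
#' @export
electrode <- function(pos, prefactor = 1, lag = NULL) {
  structure(list(pos = as.numeric(pos), prefactor = prefactor, lag = lag),
            class = "mw_electrode")
}

#' Kernel weights of an electrode over the grid
#'
#' @param grid a [grid_spec()].
#' @param inhom an [inhom_field()] (exterior vertices get weight 0).
#' @param electrode an [electrode()]. Its distance to every interior vertex
#'   must be at least half the smallest grid spacing (singular-kernel
#'   guard).
#' @return numeric vector of per-vertex weights
#'   `prefactor * voxel_volume / distance` (0 at exterior vertices).
#' @export
egm_kernel <- function(grid, inhom, electrode) {
  inhom <- as_inhom(grid, inhom)
  interior <- as.vector(inhom) > 0L
  pos <- grid_positions(grid)
  xe <- electrode$pos
  Nd <- max(ncol(pos), length(xe))
  if (ncol(pos) < Nd)
    pos <- cbind(pos, matrix(0, nrow(pos), Nd - ncol(pos)))
  if (length(xe) < Nd) xe <- c(xe, rep(0, Nd - length(xe)))
  d <- sqrt(rowSums(sweep(pos, 2, xe, `-`)^2))
  eps_singular <- min(grid$spacing) / 2
  if (any(d[interior] < eps_singular))
    stop_validation("singular kernel: electrode too close to an interior vertex")
  w <- numeric(grid$n)
  w[interior] <- electrode$prefactor * prod(grid$spacing) / d[interior]
  w
}

#' Pseudo-EGM time series from diffusion-term frames
#'
#' @param diff_frames the recorded diffusion term: a T x n matrix, a
#'   (t, x, y, z) array, or a list of per-frame layers.
#' @param kernel weights from [egm_kernel()].
#' @return numeric vector `phi_e(t)`, one value per frame.
#' @export
compute_pseudo_egm <- function(diff_frames, kernel) {
  n <- length(kernel)
  if (is.list(diff_frames)) {
    return(vapply(diff_frames, function(f) sum(kernel * as.numeric(f)), 1))
  }
  d <- dim(diff_frames)
  if (!is.null(d) && length(d) > 2)
    diff_frames <- matrix(diff_frames, nrow = d[1])
  if (is.null(dim(diff_frames))) diff_frames <- matrix(diff_frames, nrow = 1)
  if (ncol(diff_frames) != n)
    stop_validation("frame size does not match the kernel")
  as.numeric(diff_frames %*% kernel)
}
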