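#' Phase-singularity (tip / filament point) detection
#'
#' A rotor core is located where an activation isoline and a recovery
#' isoline intersect. On the grid this is found by scanning every voxel
#' face of every coordinate plane: the two chosen variables are
#' bilinearly interpolated on the face and the intersection of their
#' isolines, if any, is reported as a tip with a continuous position. In
#' N dimensions all C(N,2) coordinate-plane families are scanned, which
#' generalizes tips (2D) and filaments (3D) to superfilaments.
#'
#' @name filaments
NULL

#' Intersection of two bilinear isolines on a unit face
#'
#' Solves `f(s, t) = f_iso` and `g(s, t) = g_iso` for the bilinear
#' interpolants of the corner values on the unit square; corners are
#' ordered (0,0), (1,0), (0,1), (1,1). A constant interpolant equal to its
#' isovalue (a line, not a point) yields no reported point.
#'
#' @param f_corners,g_corners numeric(4) corner values.
#' @param f_iso,g_iso isovalues.
#' @param tol root acceptance tolerance in face-local units.
#' @return matrix with columns `s`, `t`: 0, 1 or 2 interior solutions in
#'   `[0, 1]^2`.
#' @export
bilinear_face_intersection <- function(f_corners, g_corners,
                                       f_iso = 0, g_iso = 0, tol = 1e-9) {
  a0 <- f_corners[1] - f_iso
  a1 <- f_corners[2] - f_corners[1]
  a2 <- f_corners[3] - f_corners[1]
  a3 <- f_corners[4] - f_corners[2] - f_corners[3] + f_corners[1]
  b0 <- g_corners[1] - g_iso
  b1 <- g_corners[2] - g_corners[1]
  b2 <- g_corners[3] - g_corners[1]
  b3 <- g_corners[4] - g_corners[2] - g_corners[3] + g_corners[1]
  # eliminate t: (a0 + a1 s)(b2 + b3 s) - (b0 + b1 s)(a2 + a3 s) = 0
  c2 <- a1 * b3 - b1 * a3
  c1 <- a0 * b3 + a1 * b2 - b0 * a3 - b1 * a2
  c0 <- a0 * b2 - b0 * a2
  scale <- max(abs(c(c0, c1, c2)), 1e-300)
  roots <- if (abs(c2) <= 1e-14 * scale) {
    if (abs(c1) <= 1e-14 * scale) numeric(0) else -c0 / c1
  } else {
    disc <- c1 * c1 - 4 * c2 * c0
    if (disc < 0) numeric(0) else {
      # numerically stable quadratic roots
      q <- -0.5 * (c1 + sign(c1 + (c1 == 0)) * sqrt(disc))
      unique(c(q / c2, if (q != 0) c0 / q else -c1 / c2 - q / c2))
    }
  }
  out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("s", "t")))
  fs <- max(abs(c(a0, a1, a2, a3)), 1e-300)
  gs <- max(abs(c(b0, b1, b2, b3)), 1e-300)
  for (s in roots) {
    if (!is.finite(s) || s < -tol || s > 1 + tol) next
    den_f <- a2 + a3 * s
    den_g <- b2 + b3 * s
    t <- if (abs(den_f) / fs >= abs(den_g) / gs && abs(den_f) > 0)
      -(a0 + a1 * s) / den_f
    else if (abs(den_g) > 0) -(b0 + b1 * s) / den_g
    else NA_real_
    if (!is.finite(t) || t < -tol || t > 1 + tol) next
    # both equations must actually hold (guards degenerate eliminations)
    if (abs(a0 + a1 * s + (a2 + a3 * s) * t) > 1e-8 * fs) next
    if (abs(b0 + b1 * s + (b2 + b3 * s) * t) > 1e-8 * gs) next
    sc <- min(max(s, 0), 1)
    tc <- min(max(t, 0), 1)
    if (nrow(out) && any(abs(out[, 1] - sc) < 1e-12 &
                         abs(out[, 2] - tc) < 1e-12)) next
    out <- rbind(out, c(sc, tc))
  }
  out
}

#' Detect phase singularities in a state field
#'
#' Scans every voxel face of every coordinate-plane family whose four
#' corners are interior, and reports the bilinear isoline intersections of
#' the two chosen surfaces. The surfaces are usually isolines of two state
#' variables (`vars` as column indices into `state`), but any two
#' precomputed layers can be supplied as a list (e.g. the delayed-voltage
#' pair `u(t)`, `u(t - tau)`).
#'
#' @param state n x M state matrix, or a list of two per-vertex layers.
#' @param grid a [grid_spec()].
#' @param vars pair of variable indices (ignored when `state` is a list).
#' @param iso pair of isovalues.
#' @param inhom optional [inhom_field()]; faces touching exterior corners
#'   are skipped.
#' @param t time stamp attached to the detected tips.
#' @param warn_range warn (and return no tips) when an isovalue lies
#'   outside both variables' observed range.
#' @return data frame, one row per tip: `time`, continuous position
#'   `x, y, z` (mm; absent axes 0), `plane` (e.g. `"xy"`), anchor vertex
#'   indices `i, j, k`, face-local coordinates `s, t`, isovalues.
#' @export
detect_tips <- function(state, grid, vars = c(1L, 2L), iso = c(0, 0),
                        inhom = NULL, t = NA_real_, warn_range = TRUE) {
  if (is.list(state) && !is.data.frame(state)) {
    f <- as.numeric(state[[1]]); g <- as.numeric(state[[2]])
  } else {
    f <- state[, vars[1]]; g <- state[, vars[2]]
  }
  inhom <- as_inhom(grid, inhom)
  interior <- as.vector(inhom) > 0L
  empty <- data.frame(time = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), plane = character(0), i = integer(0),
                      j = integer(0), k = integer(0), s = numeric(0),
                      t = numeric(0), iso_f = numeric(0), iso_g = numeric(0))
  fr <- range(f[interior]); gr <- range(g[interior])
  if (iso[1] < fr[1] || iso[1] > fr[2] || iso[2] < gr[1] || iso[2] > gr[2]) {
    if (warn_range)
      warning("isovalue outside the observed range; no tips detected",
              call. = FALSE)
    return(empty)
  }
  idx <- grid_indices(grid)
  st <- x_strides(grid)
  sh <- grid$shape
  N <- grid$N
  axis_names <- c("x", "y", "z", "w", "v")[seq_len(max(N, 3))]
  rows <- list()
  for (a in seq_len(N)) for (b in seq_len(N)) {
    if (b <= a) next
    # anchors with the full face in bounds
    ok <- interior & idx[, a] < sh[a] & idx[, b] < sh[b]
    v0 <- which(ok)
    if (!length(v0)) next
    va <- v0 + st[a]; vb <- v0 + st[b]; vab <- va + st[b]
    keep <- interior[va] & interior[vb] & interior[vab]
    v0 <- v0[keep]; va <- va[keep]; vb <- vb[keep]; vab <- vab[keep]
    if (!length(v0)) next
    f00 <- f[v0]; f10 <- f[va]; f01 <- f[vb]; f11 <- f[vab]
    g00 <- g[v0]; g10 <- g[va]; g01 <- g[vb]; g11 <- g[vab]
    cand <- pmin(f00, f10, f01, f11) <= iso[1] &
            pmax(f00, f10, f01, f11) >= iso[1] &
            pmin(g00, g10, g01, g11) <= iso[2] &
            pmax(g00, g10, g01, g11) >= iso[2]
    for (q in which(cand)) {
      pts <- bilinear_face_intersection(
        c(f00[q], f10[q], f01[q], f11[q]),
        c(g00[q], g10[q], g01[q], g11[q]), iso[1], iso[2])
      if (!nrow(pts)) next
      anc <- idx[v0[q], ]
      pos0 <- grid$origin + (anc - 1) * grid$spacing
      for (r in seq_len(nrow(pts))) {
        pos <- pos0
        pos[a] <- pos[a] + pts[r, 1] * grid$spacing[a]
        pos[b] <- pos[b] + pts[r, 2] * grid$spacing[b]
        pos3 <- c(pos, 0, 0)[1:3]
        anc3 <- c(anc, 1L, 1L)[1:3]
        rows[[length(rows) + 1L]] <- data.frame(
          time = t, x = pos3[1], y = pos3[2], z = pos3[3],
          plane = paste0(axis_names[a], axis_names[b]),
          i = anc3[1], j = anc3[2], k = anc3[3],
          s = pts[r, 1], t = pts[r, 2], iso_f = iso[1], iso_g = iso[2])
      }
    }
  }
  if (!length(rows)) empty else do.call(rbind, rows)
}

#' Link per-frame tips into trajectories
#'
#' Greedy nearest-neighbor matching between consecutive frames: the
#' closest (tip, trajectory-head) pair within the linking radius is matched
#' first, repeatedly. Unmatched new tips open trajectories (birth);
#' unmatched old trajectories close (death time = the first frame at which
#' the tip is gone); trajectories alive at the last frame are flagged open.
#'
#' @param tips_by_frame list of per-frame tip data frames (as from
#'   [detect_tips()]), time-ordered.
#' @param times frame times (defaults to the `time` column / frame index).
#' @param max_link_distance linking radius, mm, per frame gap.
#' @return list of trajectories: each has `points` (data frame), `birth`,
#'   `death` (NA while open) and `open`.
#' @export
link_trajectories <- function(tips_by_frame, max_link_distance,
                              times = NULL) {
  if (is.null(times))
    times <- vapply(seq_along(tips_by_frame), function(i) {
      d <- tips_by_frame[[i]]
      if (nrow(d) && is.finite(d$time[1])) d$time[1] else as.numeric(i)
    }, 1)
  trajs <- list()
  active <- integer(0)   # indices into trajs
  for (fi in seq_along(tips_by_frame)) {
    d <- tips_by_frame[[fi]]
    tnow <- times[fi]
    new_pts <- if (nrow(d)) as.matrix(d[, c("x", "y", "z")]) else
      matrix(numeric(0), 0, 3)
    matched_new <- rep(FALSE, nrow(new_pts))
    matched_act <- rep(FALSE, length(active))
    if (length(active) && nrow(new_pts)) {
      heads <- t(vapply(active, function(k) {
        p <- trajs[[k]]$points
        as.numeric(p[nrow(p), c("x", "y", "z")])
      }, numeric(3)))
      Dm <- outer(seq_len(nrow(heads)), seq_len(nrow(new_pts)),
                  Vectorize(function(r, c2)
                    sqrt(sum((heads[r, ] - new_pts[c2, ])^2))))
      repeat {
        Dm[matched_act, ] <- Inf
        Dm[, matched_new] <- Inf
        m <- which.min(Dm)
        if (!length(m) || !is.finite(Dm[m]) ||
            Dm[m] > max_link_distance) break
        r <- (m - 1) %% nrow(Dm) + 1
        c2 <- (m - 1) %/% nrow(Dm) + 1
        k <- active[r]
        trajs[[k]]$points <- rbind(trajs[[k]]$points, d[c2, , drop = FALSE])
        matched_act[r] <- TRUE
        matched_new[c2] <- TRUE
      }
    }
    # deaths
    for (r in which(!matched_act)) {
      k <- active[r]
      trajs[[k]]$death <- tnow
      trajs[[k]]$open <- FALSE
    }
    active <- active[matched_act]
    # births
    for (c2 in which(!matched_new)) {
      trajs[[length(trajs) + 1L]] <- list(points = d[c2, , drop = FALSE],
                                          birth = tnow, death = NA_real_,
                                          open = TRUE)
      active <- c(active, length(trajs))
    }
  }
  trajs
}
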