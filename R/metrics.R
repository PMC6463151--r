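# Flow analysis: stream functions, vortex detection/classification,
# velocity transects, wall shear stress, TAWSS and OSI.

# central differences on the periodic grid (rows = x, cols = y)
shift_mat <- function(A, n, dim) {
  if (dim == 1) {
    idx <- ((seq_len(nrow(A)) - 1 - n) %% nrow(A)) + 1
    A[idx, , drop = FALSE]
  } else {
    idx <- ((seq_len(ncol(A)) - 1 - n) %% ncol(A)) + 1
    A[, idx, drop = FALSE]
  }
}
ddx <- function(A, h) (shift_mat(A, -1, 1) - shift_mat(A, 1, 1)) / (2 * h)
ddy <- function(A, h) (shift_mat(A, -1, 2) - shift_mat(A, 1, 2)) / (2 * h)

#' Vorticity of a fluid state
#' @param state `fluid_state`
#' @return matrix `dv/dx - du/dy` on the grid
#' @export
vorticity <- function(state) {
  ddx(state$v, state$grid$h) - ddy(state$u, state$grid$h)
}

#' Stream function of a (divergence-free) fluid state
#'
#' Solves `lap(psi) = -omega` spectrally on the periodic domain, restores
#' the mean-flow contribution (`ubar y - vbar x`), and gauges `psi = 0` on
#' the lower channel wall.  Level curves of `psi` are streamlines:
#' `u = dpsi/dy`, `v = -dpsi/dx`.
#'
#' @param state `fluid_state`
#' @param div_tol error if the discrete divergence exceeds this tolerance
#'   (relative to `max|u|/h`), default 1e-6
#' @return object of class `stream_function_field`: list with matrix
#'   `psi`, the `grid`, and the gauge value subtracted
#' @export
stream_function <- function(state, div_tol = 1e-6) {
  g <- state$grid
  div <- ddx(state$u, g$h) + ddy(state$v, g$h)
  scale <- max(abs(state$u), abs(state$v), 1e-300) / g$h
  if (max(abs(div)) > div_tol * scale)
    stop("stream_function: input field is not divergence-free within tolerance")
  w <- ddx(state$v, g$h) - ddy(state$u, g$h)
  psi <- fft_poisson_cpp(w, g$Lx, g$Ly)
  ub <- mean(state$u); vb <- mean(state$v)
  psi <- psi + outer(rep(ub, g$Nx), g$y) - outer(vb * g$x, rep(1, g$Ny))
  gauge <- if (!is.null(state$curve$layout)) {
    j0 <- which.min(abs(g$y - state$curve$layout$y_bot))
    mean(psi[, j0])
  } else mean(psi[, 1])
  psi <- psi - gauge
  structure(list(psi = psi, grid = g, gauge = gauge),
            class = "stream_function_field")
}

# Bilinear interpolation of a grid field at arbitrary points (periodic).
bilinear <- function(A, grid, x, y) {
  gx <- x / grid$h; gy <- y / grid$h
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  i0 <- (i0 %% grid$Nx) + 1; j0 <- (j0 %% grid$Ny) + 1
  i1 <- (i0 %% grid$Nx) + 1; j1 <- (j0 %% grid$Ny) + 1
  A[cbind(i0, j0)] * (1 - fx) * (1 - fy) + A[cbind(i1, j0)] * fx * (1 - fy) +
    A[cbind(i0, j1)] * (1 - fx) * fy + A[cbind(i1, j1)] * fx * fy
}

# Closed polygon bounding the fluid region (channel + cavity), built from
# the boundary curve itself so trabecular ridges are excluded from the
# fluid.  Vertices ordered counter-clockwise.
fluid_polygon <- function(curve) {
  lay <- curve$layout
  # top points are ordered left-to-right by construction
  top <- curve$points[curve$segment == "top", , drop = FALSE]
  rbind(c(0, lay$y_bot), c(lay$Lx, lay$y_bot), c(lay$Lx, lay$y_top),
        top[rev(seq_len(nrow(top))), ], c(0, lay$y_top))
}

# Even-odd point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Region masks for a chamber geometry on a grid
#'
#' Computes logical `Nx x Ny` masks: `fluid` (inside the channel-plus-
#' cavity region bounded by the discretized boundary), `cavity` (fluid
#' above the channel's upper wall level), `intracardial`, and one
#' `intertrabecular[k]` mask per valley (cavity nodes whose nearest
#' boundary point carries that label and which lie within `hT + rT` of the
#' wall).  `interior` excludes a one-cell ring next to the boundary.
#'
#' @param curve `boundary_curve` from [build_idealized_chamber()]
#' @param grid `fluid_grid`
#' @return list of masks; intertrabecular masks are named by label
#' @export
region_masks <- function(curve, grid) {
  lay <- curve$layout
  poly <- fluid_polygon(curve)
  X <- matrix(rep(grid$x, grid$Ny), grid$Nx, grid$Ny)
  Y <- matrix(rep(grid$y, each = grid$Nx), grid$Nx, grid$Ny)
  fluid <- matrix(points_in_polygon(as.vector(X), as.vector(Y), poly),
                  grid$Nx, grid$Ny)
  cavity <- fluid & (Y > lay$y_top + 1e-9)

  # distance from cavity nodes to the boundary, and nearest labels
  idx <- which(cavity)
  bp <- curve$points
  nearest_lab <- character(length(idx)); ndist <- numeric(length(idx))
  if (length(idx)) {
    for (q in seq_along(idx)) {
      d2 <- (bp[, 1] - X[idx[q]])^2 + (bp[, 2] - Y[idx[q]])^2
      k <- which.min(d2)
      nearest_lab[q] <- curve$labels[k]
      ndist[q] <- sqrt(d2[k])
    }
  }
  interior <- fluid
  interior[idx[ndist <= 1.2 * grid$h]] <- FALSE
  # also strip the wall-adjacent ring inside the channel
  near_wall <- (abs(Y - lay$y_bot) <= 1.2 * grid$h) |
    (abs(Y - lay$y_top) <= 1.2 * grid$h & Y <= lay$y_top + 1e-9)
  interior <- interior & !near_wall

  hT <- curve$params$hT; rT <- curve$params$rT
  masks <- list(fluid = fluid, cavity = cavity, interior = interior)
  it_labs <- sort(unique(grep("^intertrabecular", curve$labels, value = TRUE)))
  intra <- cavity
  for (lb in it_labs) {
    m <- matrix(FALSE, grid$Nx, grid$Ny)
    sel <- nearest_lab == lb & ndist <= (hT + rT)
    m[idx[sel]] <- TRUE
    masks[[lb]] <- m
    intra <- intra & !m
  }
  masks$intracardial <- intra
  masks
}

#' Detect and classify closed-streamline vortices
#'
#' Finds interior local extrema of the stream function and keeps those
#' around which the `psi` contour at level `psi_ext -/+ eps * dpsi` (with
#' `dpsi` the gap between the extremum and the wall streamline) closes
#' entirely within the fluid.  Each vortex is classified by its center:
#' inside an intertrabecular mask (valley within `hT + rT` of the wall
#' between adjacent crests) it is `"intertrabecular"`, otherwise
#' `"intracardial"`.  Rotation sense follows the extremum sign (`psi`
#' maximum = counter-clockwise).
#'
#' @param psi `stream_function_field` (or a `fluid_state`, in which case
#'   the stream function is computed first)
#' @param curve `boundary_curve`
#' @param masks optional precomputed [region_masks()]
#' @param eps closedness threshold as a fraction of the extremum-to-wall
#'   `psi` gap, default 0.05
#' @param min_depth minimum `psi` gap relative to the global fluid `psi`
#'   range for an extremum to count, default 1e-4 (rejects round-off
#'   ripples)
#' @param min_cells minimum enclosed contour area in grid-cell units
#'   (`h^2`), default 1: a recirculation smaller than one cell is below
#'   the resolution floor and is not reported
#' @return object of class `vortex_report`: data frame with columns `x`,
#'   `y`, `class`, `region`, `sense`, `extent` (contour area as a fraction
#'   of the chamber area), `depth`
#' @export
detect_vortices <- function(psi, curve = NULL, masks = NULL, eps = 0.05,
                            min_depth = 1e-4, min_cells = 1) {
  if (inherits(psi, "fluid_state")) psi <- stream_function(psi)
  g <- psi$grid
  P <- psi$psi
  if (is.null(curve)) {
    # generic field on the full domain (constructed-psi oracles)
    fluid <- matrix(TRUE, g$Nx, g$Ny)
    interior <- fluid
    interior[c(1, g$Nx), ] <- FALSE; interior[, c(1, g$Ny)] <- FALSE
    masks <- list(fluid = fluid, cavity = interior, interior = interior)
    poly <- rbind(c(0, 0), c(g$Lx - g$h, 0), c(g$Lx - g$h, g$Ly - g$h),
                  c(0, g$Ly - g$h))
  } else {
    if (is.null(masks)) masks <- region_masks(curve, g)
    poly <- fluid_polygon(curve)
  }
  cand_mask <- masks$cavity & masks$interior
  rng <- diff(range(P[masks$fluid]))
  empty <- data.frame(x = numeric(0), y = numeric(0), class = character(0),
                      region = character(0), sense = character(0),
                      extent = numeric(0), depth = numeric(0))
  if (!any(cand_mask) || rng == 0)
    return(structure(empty, class = c("vortex_report", "data.frame")))

  idx <- which(cand_mask, arr.ind = TRUE)
  cands <- list()
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]; j <- idx[q, 2]
    if (i < 2 || i > g$Nx - 1 || j < 2 || j > g$Ny - 1) next
    nb <- P[(i - 1):(i + 1), (j - 1):(j + 1)]
    nbf <- masks$fluid[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (sum(nbf) < 7) next
    v0 <- P[i, j]
    others <- nb[-5][nbf[-5]]
    if (all(v0 > others)) {
      cands[[length(cands) + 1]] <- list(i = i, j = j, sign = 1)
    } else if (all(v0 < others)) {
      cands[[length(cands) + 1]] <- list(i = i, j = j, sign = -1)
    }
  }
  if (!length(cands))
    return(structure(empty, class = c("vortex_report", "data.frame")))

  if (!is.null(curve)) {
    chamber_area <- pi * curve$params$aV * curve$params$bV / 2
    bp <- curve$points
  } else {
    chamber_area <- g$Lx * g$Ly
    bp <- NULL
  }
  psi_bg <- stats::median(P[masks$fluid])
  out <- empty
  contours <- list()
  # reference streamline: the nearest wall point (chamber runs) or the
  # background level (generic fields)
  for (cd in cands) {
    x0 <- g$x[cd$i]; y0 <- g$y[cd$j]
    psi_wall <- if (!is.null(bp)) {
      d2 <- (bp[, 1] - x0)^2 + (bp[, 2] - y0)^2
      k <- which.min(d2)
      bilinear(P, g, bp[k, 1], bp[k, 2])
    } else psi_bg
    pext <- P[cd$i, cd$j]
    depth <- abs(pext - psi_wall)
    if (depth < min_depth * rng) next
    closed_contour_at <- function(frac) {
      lev <- pext - cd$sign * frac * depth
      for (cl in contourLines(g$x, g$y, P, levels = lev)) {
        n <- length(cl$x)
        if (n < 4) next
        if (abs(cl$x[1] - cl$x[n]) > 1e-9 || abs(cl$y[1] - cl$y[n]) > 1e-9) next
        if (!points_in_polygon(x0, y0, cbind(cl$x, cl$y))) next
        if (!all(points_in_polygon(cl$x, cl$y, poly))) next
        return(cl)
      }
      NULL
    }
    # the vortex exists if the contour close to the extremum (at eps of
    # the extremum-to-wall gap) closes inside the fluid
    found <- closed_contour_at(eps)
    if (is.null(found)) next
    core_area <- abs(sum(found$x * c(found$y[-1], found$y[1]) -
                         c(found$x[-1], found$x[1]) * found$y) / 2)
    if (core_area < min_cells * g$h^2) next
    # its extent is measured at the widest level that still closes
    # (approaching the separatrix / wall streamline)
    for (frac in c(0.95, 0.9, 0.8, 0.65, 0.5, 0.35, 0.2)) {
      wide <- closed_contour_at(frac)
      if (!is.null(wide)) { found <- wide; break }
    }
    area <- abs(sum(found$x * c(found$y[-1], found$y[1]) -
                    c(found$x[-1], found$x[1]) * found$y) / 2)
    reg <- if (!is.null(curve)) classify_center(cd$i, cd$j, curve, g) else "interior"
    cls_name <- if (grepl("^intertrabecular", reg)) "intertrabecular"
                else if (reg == "interior") "interior" else "intracardial"
    out <- rbind(out, data.frame(
      x = x0, y = y0, class = cls_name, region = reg,
      sense = if (cd$sign > 0) "ccw" else "cw",
      extent = area / chamber_area, depth = depth))
    contours[[nrow(out)]] <- found
  }
  # de-duplicate: drop a vortex whose center lies inside an accepted
  # deeper vortex's contour with the same rotation sense
  if (nrow(out) > 1) {
    ord <- order(-out$depth)
    keep <- rep(TRUE, nrow(out))
    acc <- integer(0)
    for (r in ord) {
      dup <- FALSE
      for (a in acc) {
        if (out$sense[a] == out$sense[r] &&
            points_in_polygon(out$x[r], out$y[r],
                              cbind(contours[[a]]$x, contours[[a]]$y))) {
          dup <- TRUE
          break
        }
      }
      if (dup) keep[r] <- FALSE else acc <- c(acc, r)
    }
    out <- out[keep, , drop = FALSE]
    contours <- contours[keep]
  }
  rownames(out) <- NULL
  attr(out, "contours") <- contours
  structure(out, class = c("vortex_report", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Region of a grid node: nearest boundary label (if within hT + rT) else
# intracardial.
classify_center <- function(i, j, curve, grid) {
  x0 <- grid$x[i]; y0 <- grid$y[j]
  bp <- curve$points
  d2 <- (bp[, 1] - x0)^2 + (bp[, 2] - y0)^2
  k <- which.min(d2)
  lb <- curve$labels[k]
  reach <- curve$params$hT + curve$params$rT
  if (grepl("^intertrabecular", lb) && sqrt(d2[k]) <= reach) lb else "intracardial"
}

#' @export
print.vortex_report <- function(x, ...) {
  cat("Vortex report:", nrow(x), "vortices\n")
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

#' Velocity transect between two points
#'
#' Samples the velocity field by bilinear interpolation at `n` uniform
#' positions along the straight segment from `p0` (e.g. the AV-canal or
#' chamber center) to `p1` (a wall point in an intertrabecular region).
#'
#' @param state `fluid_state`
#' @param p0,p1 segment endpoints (2-vectors, inside the domain)
#' @param n number of samples, default 128 (>= 100 recommended)
#' @return object of class `transect`: data frame with `s` (normalized
#'   0 to 1 position), `x`, `y`, `u`, `v`, `speed`
#' @export
velocity_transect <- function(state, p0, p1, n = 128) {
  g <- state$grid
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] >= g$Lx || p[2] < 0 || p[2] >= g$Ly)
      stop("transect endpoint outside the domain")
  }
  s <- seq(0, 1, length.out = n)
  x <- p0[1] + s * (p1[1] - p0[1])
  y <- p0[2] + s * (p1[2] - p0[2])
  u <- bilinear(state$u, g, x, y)
  v <- bilinear(state$v, g, x, y)
  structure(data.frame(s = s, x = x, y = y, u = u, v = v,
                       speed = sqrt(u^2 + v^2)),
            class = c("transect", "data.frame"))
}

#' Wall shear stress along the boundary
#'
#' Estimates the WSS vector at every boundary point as
#' `mu * du_t/dn * t_hat`.  The tangential velocity is sampled at offsets
#' `1.5h` to `3h` along the inward normal (outside the core of the
#' regularized delta kernel, where the velocity profile is resolved), a
#' quadratic is fitted by least squares, and the wall-normal gradient is
#' evaluated at the fit's own zero crossing -- the hydrodynamically
#' effective wall position, which for a kernel-smeared immersed boundary
#' sits a fraction of a cell inside the nominal wall.  For exactly
#' quadratic profiles through the wall (closed-form channel flow sampled
#' analytically) the estimate is exact.  Probe points that leave the
#' fluid (deep concavities) are flagged `NA` and excluded from averages.
#'
#' @param state `fluid_state`
#' @param curve `boundary_curve`; target positions and inward normals are
#'   used (the tethered wall's rest shape)
#' @param mu dynamic viscosity; defaults to the run's `nu` (unit density)
#' @return n x 2 matrix of WSS vectors with attribute `"flagged"` (logical)
#' @export
wall_shear_stress <- function(state, curve, mu = state$flow$nu %||% 1) {
  g <- state$grid
  h <- g$h
  p <- curve$target
  nn <- curve$normals
  tt <- cbind(nn[, 2], -nn[, 1])   # tangent, right-handed w.r.t. inward normal
  offs <- c(1.5, 2, 2.5, 3) * h
  ut <- matrix(0, nrow(p), length(offs))
  inside <- matrix(TRUE, nrow(p), length(offs))
  poly <- if (!is.null(curve$layout)) fluid_polygon(curve)
  for (k in seq_along(offs)) {
    q <- cbind((p[, 1] + offs[k] * nn[, 1]) %% g$Lx,
               (p[, 2] + offs[k] * nn[, 2]) %% g$Ly)
    uq <- bilinear(state$u, g, q[, 1], q[, 2])
    vq <- bilinear(state$v, g, q[, 1], q[, 2])
    ut[, k] <- uq * tt[, 1] + vq * tt[, 2]
    if (!is.null(poly))
      inside[, k] <- points_in_polygon(q[, 1], q[, 2], poly)
  }
  # least-squares quadratic ut(d) = c0 + c1 d + c2 d^2 (same design for
  # every point)
  X <- cbind(1, offs, offs^2)
  P <- solve(crossprod(X), t(X))
  cf <- ut %*% t(P)                      # n x 3: c0, c1, c2
  c0 <- cf[, 1]; c1 <- cf[, 2]; c2 <- cf[, 3]
  # zero crossing nearest the nominal wall (clamped to about one cell)
  disc <- c1^2 - 4 * c2 * c0
  lin <- abs(c2) < 1e-12 | disc < 0
  r1 <- ifelse(lin, 0, (-c1 + sqrt(pmax(disc, 0))) / (2 * c2))
  r2 <- ifelse(lin, 0, (-c1 - sqrt(pmax(disc, 0))) / (2 * c2))
  d0 <- ifelse(lin, ifelse(abs(c1) > 1e-12, -c0 / c1, 0),
               ifelse(abs(r1) < abs(r2), r1, r2))
  d0 <- pmin(pmax(d0, -h), 1.5 * h)
  dudn <- c1 + 2 * c2 * d0
  wss <- mu * dudn * tt
  flagged <- !apply(inside, 1, all)
  wss[flagged, ] <- NA_real_
  attr(wss, "flagged") <- flagged
  wss
}

# periodic trapezoidal quadrature weights for sample times (fractions of
# one cycle, in (0, 1])
cycle_weights <- function(times) {
  n <- length(times)
  tim <- c(times[n] - 1, times, times[1] + 1)
  w <- (tim[3:(n + 2)] - tim[1:n]) / 2
  w / sum(w)
}

#' Time-averaged WSS and oscillatory shear index
#'
#' From one cycle of WSS vector samples: TAWSS is the magnitude of the
#' time-mean WSS vector; the OSI,
#' `0.5 * (1 - |mean vector| / mean |vector|)`, measures how aligned the
#' instantaneous WSS is with its time average: 0 for unidirectional shear,
#' 0.5 for perfectly reversing shear.  Zero-mean-magnitude points have
#' OSI defined as 0.
#'
#' @param shear a `shear_record` (from [run_pulsatile()]) or a list with
#'   `times` (cycle fractions) and `wss` (list of n x 2 matrices)
#' @return data frame with per-point `tawss`, `mean_mag`, `osi` (all in
#'   `[0, 0.5]` for `osi`) and the region `label`
#' @export
tawss_osi <- function(shear) {
  w <- cycle_weights(shear$times)
  n <- nrow(shear$wss[[1]])
  mx <- my <- mm <- rep(0, n)
  for (k in seq_along(w)) {
    mx <- mx + w[k] * shear$wss[[k]][, 1]
    my <- my + w[k] * shear$wss[[k]][, 2]
    mm <- mm + w[k] * sqrt(rowSums(shear$wss[[k]]^2))
  }
  tawss <- sqrt(mx^2 + my^2)
  osi <- ifelse(mm > 0, 0.5 * (1 - pmin(tawss / mm, 1)), 0)
  data.frame(tawss = tawss, mean_mag = mm, osi = osi,
             label = shear$labels %||% rep(NA_character_, n))
}

#' Arc-length-weighted regional average
#'
#' Averages a per-boundary-point quantity over the points carrying a
#' region label.  Matching is by prefix: `region = "trabecula"` covers all
#' `trabecula[k]`, `region = "ventricle"` covers the whole cavity lining
#' (trabeculae, intertrabecular regions and chamber wall), and an exact
#' label such as `"intertrabecular[3]"` selects one region.  Points are
#' uniformly spaced so the arc-length weighting is a plain mean; `NA`
#' (flagged) points are excluded.
#'
#' @param values numeric vector (one value per boundary point) or a matrix
#'   with one row per time sample
#' @param curve `boundary_curve` (or a character vector of labels)
#' @param region region name or prefix
#' @return scalar, or one value per row of `values`
#' @export
region_average <- function(values, curve, region) {
  labels <- if (inherits(curve, "boundary_curve")) curve$labels else curve
  sel <- if (region == "ventricle") {
    grepl("^(trabecula|intertrabecular|chamber-wall)", labels)
  } else if (grepl("\\[", region)) {
    labels == region
  } else {
    startsWith(labels, region)
  }
  if (!any(sel)) stop(sprintf("region '%s' is empty", region))
  if (is.matrix(values)) {
    rowMeans(values[, sel, drop = FALSE], na.rm = TRUE)
  } else {
    mean(values[sel], na.rm = TRUE)
  }
}

#' Tangential wall velocity along the cavity lining
#'
#' Samples the velocity at an offset along the inward normal from each
#' cavity-lining point and projects it on the local downstream tangent.
#' Used to diagnose wall flow reversal (negative values) when an
#' intracardial vortex forms.
#'
#' @param state `fluid_state`
#' @param curve `boundary_curve`
#' @param offset sampling offset along the inward normal, default `2 h`
#' @return data frame with point index, `x`, `y`, `label`, `ut`
#' @export
wall_tangential_velocity <- function(state, curve, offset = 2 * state$grid$h) {
  g <- state$grid
  on_arc <- grepl("^(trabecula|intertrabecular|chamber-wall)", curve$labels)
  p <- curve$target[on_arc, , drop = FALSE]
  nn <- curve$normals[on_arc, , drop = FALSE]
  # downstream tangent: for the upper (cavity) wall ordered left-to-right
  # with inward normal pointing down/in, the downstream direction is
  # (-n_y, n_x) rotated so that it has positive x on average
  tt <- cbind(-nn[, 2], nn[, 1])
  if (mean(tt[, 1]) < 0) tt <- -tt
  q <- cbind((p[, 1] + offset * nn[, 1]) %% g$Lx,
             (p[, 2] + offset * nn[, 2]) %% g$Ly)
  u <- bilinear(state$u, g, q[, 1], q[, 2])
  v <- bilinear(state$v, g, q[, 1], q[, 2])
  data.frame(index = which(on_arc), x = p[, 1], y = p[, 2],
             label = curve$labels[on_arc], ut = u * tt[, 1] + v * tt[, 2])
}

#' Trace a streamline by RK4 particle integration
#'
#' Integrates `dx/dt = u(x)` with classical RK4 and bilinear velocity
#' interpolation; independent cross-check for the contour-based vortex
#' detector (a particle seeded in a closed vortex returns near its start).
#'
#' @param state `fluid_state`
#' @param start 2-vector starting position
#' @param dt integration step
#' @param nsteps number of steps
#' @return matrix of positions (`nsteps + 1` rows)
#' @export
trace_streamline <- function(state, start, dt, nsteps) {
  g <- state$grid
  vel <- function(p) {
    px <- p[1] %% g$Lx; py <- p[2] %% g$Ly
    c(bilinear(state$u, g, px, py), bilinear(state$v, g, px, py))
  }
  path <- matrix(NA_real_, nsteps + 1, 2)
  p <- start
  path[1, ] <- p
  for (s in seq_len(nsteps)) {
    k1 <- vel(p)
    k2 <- vel(p + dt / 2 * k1)
    k3 <- vel(p + dt / 2 * k2)
    k4 <- vel(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    path[s + 1, ] <- p
  }
  path
}
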