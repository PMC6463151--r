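#' Geometric parameters of the idealized trabeculated chamber
#'
#' The ventricle is idealized as a half ellipse (semi-major axis `aV`,
#' semi-minor axis `bV`) laid tangentially into a straight channel of width
#' `wAV` (the atrioventricular canal, equal in width to the sinus venosus
#' `wSV`), forming a cavity-flow geometry.  `n_trab` equally spaced
#' trabeculae of radius `rT` and height `hT` protrude from the elliptical
#' wall into the chamber along the local inward normal.  All lengths are
#' dimensionless, with the channel width `wAV = 0.8` setting the scale.
#'
#' @param aV chamber semi-major axis (half-width), default 1.0
#' @param bV chamber semi-minor axis (depth), default 0.8
#' @param wAV inflow channel (AV canal) width, default 0.8
#' @param wSV outflow (sinus venosus) width; must equal `wAV`, default 0.8
#' @param rT trabecula radius, default 0.10
#' @param hT trabecula height; `hT = 0` gives a smooth chamber.  The
#'   biologically relevant height is `hT/bV = 0.08`.
#' @param n_trab number of trabeculae, default 6
#' @param ds_frac Lagrangian point spacing as a fraction of the grid
#'   spacing, default 0.5
#' @return object of class `geometry_params`
#' @export
geometry_params <- function(aV = 1.0, bV = 0.8, wAV = 0.8, wSV = 0.8,
                            rT = 0.10, hT = 0.08 * 0.8, n_trab = 6,
                            ds_frac = 0.5) {
  if (aV <= 0 || bV <= 0 || wAV <= 0 || wSV <= 0 || rT <= 0)
    stop("aV, bV, wAV, wSV, rT must all be positive")
  if (hT < 0) stop("trabecula height hT must be non-negative")
  if (hT >= bV) stop("trabecula height hT must be smaller than chamber depth bV")
  if (abs(wAV - wSV) > 1e-12)
    stop("idealized model requires wAV == wSV")
  structure(list(aV = aV, bV = bV, wAV = wAV, wSV = wSV, rT = rT, hT = hT,
                 n_trab = as.integer(n_trab), ds_frac = ds_frac),
            class = "geometry_params")
}

#' Trabecula height profile
#'
#' Perturbed-Gaussian ridge profile used for the idealized trabeculae:
#' `hT * (1 - (x/rT)^2) * exp(-(x/(0.7 rT))^8)`, clamped to zero for
#' `|x| >= rT` so that trabeculae protrude into, never out of, the wall.
#' `x` is the (signed) arc-length offset from the trabecula center.
#'
#' @param x offset(s) from the trabecula center
#' @param hT trabecula height (>= 0)
#' @param rT trabecula radius (> 0)
#' @return height above the wall, same length as `x`; even in `x`, maximal
#'   (`= hT`) at `x = 0`, zero for `|x| >= rT`
#' @examples
#' trabecula_profile(0, hT = 0.064, rT = 0.1)        # = hT
#' trabecula_profile(0.1, hT = 0.064, rT = 0.1)      # = 0 at the rim
#' @export
trabecula_profile <- function(x, hT, rT) {
  if (rT <= 0) stop("trabecula radius rT must be positive")
  if (hT < 0) stop("trabecula height hT must be non-negative")
  out <- hT * (1 - (x / rT)^2) * exp(-(x / (0.7 * rT))^8)
  out[abs(x) >= rT] <- 0
  out
}

# Resample an ordered polyline at (near-)uniform spacing ds.  Returns the
# resampled points and, for each, the arc-length position along the input.
# For closed = TRUE the last input point is assumed to wrap to the first.
resample_polyline <- function(pts, ds, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n <- max(4L, round(L / ds))
  starget <- if (closed) (0:(n - 1)) * L / n else seq(0, L, length.out = n + 1)
  x <- approx(s, pts[, 1], xout = starget, ties = "ordered")$y
  y <- approx(s, pts[, 2], xout = starget, ties = "ordered")$y
  list(points = cbind(x, y), s = starget, length = L)
}

# Normals from local tangents; side = "left" rotates the tangent +90
# degrees (counter-clockwise), side = "right" -90 degrees.
polyline_normals <- function(pts, side = "right", closed = FALSE) {
  n <- nrow(pts)
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  prv <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  tx <- pts[nxt, 1] - pts[prv, 1]
  ty <- pts[nxt, 2] - pts[prv, 2]
  len <- sqrt(tx^2 + ty^2)
  tx <- tx / len; ty <- ty / len
  if (side == "right") cbind(ty, -tx) else cbind(-ty, tx)
}

new_boundary_curve <- function(points, normals, labels, ds, params = NULL,
                               layout = NULL, segment = NULL) {
  stopifnot(nrow(points) == length(labels), nrow(points) == nrow(normals))
  structure(list(points = points, normals = normals, labels = labels,
                 target = points, ds = ds, params = params, layout = layout,
                 segment = segment),
            class = "boundary_curve")
}

#' Default domain layout for the idealized chamber
#'
#' The chamber-plus-channel geometry is embedded in a doubly periodic
#' rectangular domain.  The channel runs along x (inflow on the left / AV
#' side, outflow on the right / SV side); the half-elliptical cavity opens
#' into the upper channel wall at `xc`.  Clearances of at least one channel
#' width separate the geometry from the periodic domain edges.
#'
#' @param params `geometry_params`
#' @return list with domain extents `Lx`, `Ly`, channel wall heights
#'   `y_bot`, `y_top`, cavity center `xc`, and the inflow-band x-range
#' @export
chamber_layout <- function(params) {
  w <- params$wAV
  sc <- w / 0.8
  list(Lx = 6.4 * sc, Ly = 3.2 * sc,
       y_bot = w, y_top = 2 * w, xc = 3.2 * sc,
       band_x = c(0.4, 1.4) * sc, probe_x = 1.8 * sc)
}

#' Build the discretized idealized trabeculated chamber
#'
#' Constructs the Lagrangian boundary of the idealized geometry: a straight
#' channel of width `wAV` whose upper wall opens into a half-elliptical
#' cavity carrying `n_trab` equally spaced (in arc length, symmetric about
#' the cavity midline) trabeculae.  Trabecular ridges follow
#' [trabecula_profile()] applied along the local inward normal of the
#' ellipse.  Points are spaced `ds = ds_frac * h` apart; target (tether)
#' positions coincide with the constructed points.
#'
#' Per-point region labels: `"channel-wall"` for the straight walls,
#' `"chamber-wall"` for a smooth (`hT = 0`) cavity arc, otherwise
#' `"trabecula[k]"` within one radius of crest k and `"intertrabecular[k]"`
#' for the valley following crest k (`k = 0` and `k = n_trab` are the
#' flanking regions at the cavity edges).
#'
#' @param params `geometry_params`
#' @param h Eulerian grid spacing the boundary will be coupled to
#' @param layout domain layout, default [chamber_layout()]
#' @return object of class `boundary_curve`: ordered points, inward unit
#'   normals, labels, target positions, spacing `ds`
#' @export
build_idealized_chamber <- function(params, h, layout = chamber_layout(params)) {
  stopifnot(inherits(params, "geometry_params"), h > 0)
  ds <- params$ds_frac * h
  aV <- params$aV; bV <- params$bV; rT <- params$rT; hT <- params$hT
  nT <- params$n_trab
  xc <- layout$xc; ytop <- layout$y_top

  # fine parametrization of the elliptical arc, left to right
  th <- seq(pi, 0, length.out = 4001)
  ax <- xc + aV * cos(th)
  ay <- ytop + bV * sin(th)
  seg <- sqrt(diff(ax)^2 + diff(ay)^2)
  sarc <- c(0, cumsum(seg))
  Larc <- sarc[length(sarc)]

  centers <- Larc * (2 * seq_len(nT) - 1) / (2 * nT)
  if (nT > 1 && (centers[2] - centers[1]) < 2 * rT)
    stop("trabecula overlap: arc spacing between crests is below 2*rT")

  height <- rep(0, length(sarc))
  if (hT > 0) {
    for (ck in centers) height <- height + trabecula_profile(sarc - ck, hT, rT)
  }
  # inward normal of the ellipse (pointing into the cavity)
  nlen <- sqrt((bV * cos(th))^2 + (aV * sin(th))^2)
  nx <- -bV * cos(th) / nlen
  ny <- -aV * sin(th) / nlen
  arc <- cbind(ax + height * nx, ay + height * ny)

  # assemble the full upper boundary as one polyline: left wall, arc, right
  # wall; the bottom wall is a separate periodic line.
  nl <- max(2, ceiling((xc - aV) / ds))
  left <- cbind(seq(0, xc - aV, length.out = nl), ytop)
  nr <- max(2, ceiling((layout$Lx - xc - aV) / ds))
  right <- cbind(seq(xc + aV, layout$Lx, length.out = nr), ytop)
  top_fine <- rbind(left, arc[-1, ], right[-1, ])
  # arc-length position of the arc within the fine top polyline
  segs_top <- sqrt(diff(top_fine[, 1])^2 + diff(top_fine[, 2])^2)
  s_top <- c(0, cumsum(segs_top))
  arc_start <- s_top[nl]                 # junction at (xc - aV, ytop)
  s_of_arc <- s_top[nl:(nl + length(th) - 1)] - arc_start

  rtop <- resample_polyline(top_fine, ds, closed = FALSE)
  # drop the final point (periodic duplicate of x = Lx ~ x = 0 wall level)
  keep <- seq_len(nrow(rtop$points) - 1)
  tpts <- rtop$points[keep, , drop = FALSE]
  ts <- rtop$s[keep]

  # map resampled arc positions back to original ellipse arc length
  labels <- rep("channel-wall", nrow(tpts))
  on_arc <- ts > arc_start & ts < arc_start + max(s_of_arc)
  if (any(on_arc)) {
    s_orig <- approx(s_of_arc, sarc, xout = ts[on_arc] - arc_start,
                     ties = "ordered")$y
    if (hT == 0) {
      labels[on_arc] <- "chamber-wall"
    } else {
      lab <- character(length(s_orig))
      for (i in seq_along(s_orig)) {
        d <- s_orig[i] - centers
        k <- which(abs(d) <= rT)
        if (length(k) > 0) {
          lab[i] <- sprintf("trabecula[%d]", k[1])
        } else {
          lab[i] <- sprintf("intertrabecular[%d]", sum(d > 0))
        }
      }
      labels[on_arc] <- lab
    }
  }
  ntop <- polyline_normals(tpts, side = "right", closed = FALSE)

  nb <- max(4L, round(layout$Lx / ds))
  bx <- (0:(nb - 1)) * layout$Lx / nb
  bpts <- cbind(bx, layout$y_bot)
  nbot <- cbind(rep(0, nb), rep(1, nb))   # inward = up into the channel

  pts <- rbind(tpts, bpts)
  nrm <- rbind(ntop, nbot)
  labs <- c(labels, rep("channel-wall", nb))
  segm <- c(rep("top", nrow(tpts)), rep("bottom", nb))
  curve <- new_boundary_curve(pts, nrm, labs, ds, params = params,
                              layout = layout, segment = segm)
  curve$arc_s <- c(ifelse(on_arc, approx(s_of_arc, sarc, xout = ts - arc_start,
                                         ties = "ordered")$y, NA),
                   rep(NA, nb))
  curve$trab_centers_s <- centers
  curve$arc_length <- Larc
  curve
}

#' Build a plain periodic channel (no cavity)
#'
#' Two straight tethered walls spanning the periodic domain; used for
#' validating the solver against plane Poiseuille flow.
#'
#' @param params `geometry_params` (channel width `wAV`)
#' @param h Eulerian grid spacing
#' @param layout domain layout, default [chamber_layout()]
#' @return `boundary_curve` with all points labeled `"channel-wall"`
#' @export
build_channel <- function(params, h, layout = chamber_layout(params)) {
  ds <- params$ds_frac * h
  n <- max(4L, round(layout$Lx / ds))
  xs <- (0:(n - 1)) * layout$Lx / n
  pts <- rbind(cbind(xs, layout$y_top), cbind(xs, layout$y_bot))
  nrm <- rbind(cbind(rep(0, n), rep(-1, n)), cbind(rep(0, n), rep(1, n)))
  labs <- rep("channel-wall", 2 * n)
  segm <- c(rep("top", n), rep("bottom", n))
  new_boundary_curve(pts, nrm, labs, ds, params = params, layout = layout,
                     segment = segm)
}

#' Specification for a synthetic "realistic-like" ventricle outline
#'
#' Describes a randomized closed ventricle outline emulating traced embryo
#' geometries: a smooth periodic spline through perturbed control points on
#' an elliptical base shape, with `n_trab` inward trabecular protrusions of
#' random depth on the wall opposite the inflow/outflow gaps.
#'
#' @param n_trab number of trabecular protrusions
#' @param depth_mean,depth_sd mean and sd of protrusion depth, as a
#'   fraction of the chamber width (2 a); depths are clamped non-negative
#' @param smoothness number of spline control points for the base outline
#' @param seed RNG seed; outlines are reproducible for a fixed seed
#' @param a,b base outline semi-axes
#' @param ds point spacing of the discretized outline
#' @return object of class `synthetic_ventricle_spec`
#' @export
synthetic_ventricle_spec <- function(n_trab = 6, depth_mean = 0.08,
                                     depth_sd = 0.02, smoothness = 24,
                                     seed = 1, a = 1.0, b = 0.8, ds = 0.02) {
  if (depth_mean < 0) stop("depth_mean must be non-negative")
  if (depth_sd < 0) stop("depth_sd must be non-negative")
  structure(list(n_trab = as.integer(n_trab), depth_mean = depth_mean,
                 depth_sd = depth_sd, smoothness = as.integer(smoothness),
                 seed = as.integer(seed), a = a, b = b, ds = ds),
            class = "synthetic_ventricle_spec")
}

#' Build a synthetic ventricle outline
#'
#' Generates a closed, smooth, non-self-intersecting ventricle outline from
#' a [synthetic_ventricle_spec()].  The outline is built in polar form
#' about its centroid (which guarantees a star-shaped, non-intersecting
#' curve): a periodic smoothing spline through randomly perturbed control
#' radii of an elliptical base, minus [trabecula_profile()]-shaped inward
#' bumps at jittered, roughly equally spaced angles on the wall opposite
#' the openings.  Two angular gaps on the lower wall represent the AV-canal
#' inlet and sinus-venosus outlet.  If random depths drive the radius below
#' a positive floor, the outline is regenerated with halved `depth_sd` (up
#' to 5 retries).
#'
#' @param spec `synthetic_ventricle_spec`
#' @param center 2-vector; outline centroid position
#' @return `boundary_curve` with labels `"trabecula[k]"`,
#'   `"intertrabecular[k]"`, `"chamber-wall"` and `"channel-wall"` (gap
#'   shoulders)
#' @export
build_synthetic_ventricle <- function(spec, center = c(0, 0)) {
  stopifnot(inherits(spec, "synthetic_ventricle_spec"))
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(spec$seed)

  a <- spec$a; b <- spec$b
  depth_sd <- spec$depth_sd
  for (attempt in 1:5) {
    m <- spec$smoothness
    phic <- 2 * pi * (0:(m - 1)) / m
    r0 <- a * b / sqrt((b * cos(phic))^2 + (a * sin(phic))^2)
    rc <- r0 * (1 + rnorm(m, 0, 0.02))
    sf <- splinefun(c(phic, 2 * pi), c(rc, rc[1]), method = "periodic")
    phi <- seq(0, 2 * pi, length.out = 2001)[-2001]
    rbase <- sf(phi)

    # protrusions on the upper wall (opposite the openings), jittered
    if (spec$n_trab > 0 && spec$depth_mean > 0) {
      span <- c(pi / 6, 5 * pi / 6)
      cen <- seq(span[1], span[2], length.out = spec$n_trab + 2)[-c(1, spec$n_trab + 2)]
      cen <- cen + rnorm(spec$n_trab, 0, 0.1 * diff(span) / max(spec$n_trab, 1))
      depth <- pmax(0, rnorm(spec$n_trab, spec$depth_mean, depth_sd)) * 2 * a
      halfw <- 0.35 * diff(span) / spec$n_trab
      warc <- halfw * mean(rbase)          # bump half-width in arc units
      r <- rbase
      for (k in seq_len(spec$n_trab)) {
        darc <- (phi - cen[k]) * rbase     # angular offset in arc units
        r <- r - trabecula_profile(darc, depth[k], warc)
      }
    } else {
      r <- rbase
      cen <- numeric(0)
      depth <- numeric(0)
      halfw <- 0
    }
    if (min(r) > 0.15 * b) break
    depth_sd <- depth_sd / 2
    if (attempt == 5) stop("synthetic outline self-intersects; depths too deep")
  }

  # inlet / outlet gaps on the lower wall
  gaps <- list(c(200, 240) * pi / 180, c(300, 340) * pi / 180)
  in_gap <- (phi > gaps[[1]][1] & phi < gaps[[1]][2]) |
            (phi > gaps[[2]][1] & phi < gaps[[2]][2])

  labels <- rep("chamber-wall", length(phi))
  if (length(cen) > 0) {
    for (k in seq_along(cen)) {
      on_k <- abs((phi - cen[k]) * rbase) <= warc & depth[k] > 0
      labels[on_k] <- sprintf("trabecula[%d]", k)
    }
    for (k in 0:length(cen)) {
      lo <- if (k == 0) pi / 6 else cen[k]
      hi <- if (k == length(cen)) 5 * pi / 6 else cen[k + 1]
      mid <- phi > lo & phi < hi & labels == "chamber-wall"
      labels[mid] <- sprintf("intertrabecular[%d]", k)
    }
  }
  near_gap <- rep(FALSE, length(phi))
  for (g in gaps) {
    near_gap <- near_gap | (abs(phi - g[1]) < 0.1) | (abs(phi - g[2]) < 0.1)
  }
  labels[near_gap & !in_gap] <- "channel-wall"

  keep <- !in_gap
  pts <- cbind(center[1] + r[keep] * cos(phi[keep]),
               center[2] + r[keep] * sin(phi[keep]))
  lab <- labels[keep]

  # resample each contiguous open piece at ds
  brk <- c(0, which(diff(which(keep)) > 1), sum(keep))
  allp <- NULL; alll <- character(0); alln <- NULL
  for (i in seq_len(length(brk) - 1)) {
    idx <- (brk[i] + 1):brk[i + 1]
    if (length(idx) < 4) next
    rs <- resample_polyline(pts[idx, , drop = FALSE], spec$ds)
    seg_s <- c(0, cumsum(sqrt(diff(pts[idx, 1])^2 + diff(pts[idx, 2])^2)))
    li <- sapply(rs$s, function(sv) lab[idx[which.min(abs(seg_s - sv))]])
    nn <- polyline_normals(rs$points, side = "left", closed = FALSE)
    # orient inward (toward the centroid)
    tocen <- cbind(center[1] - rs$points[, 1], center[2] - rs$points[, 2])
    flip <- rowSums(nn * tocen) < 0
    nn[flip, ] <- -nn[flip, ]
    allp <- rbind(allp, rs$points); alll <- c(alll, li); alln <- rbind(alln, nn)
  }
  curve <- new_boundary_curve(allp, alln, alll, spec$ds, params = spec)
  curve$center <- center
  curve
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat("Boundary curve:", nrow(x$points), "Lagrangian points, ds =",
      format(x$ds, digits = 4), "\n")
  tab <- table(sub("\\[.*", "", x$labels))
  cat("Regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.boundary_curve <- function(x, ...) {
  plot(x$points, asp = 1, pch = ".", cex = 2,
       col = factor(sub("\\[.*", "", x$labels)),
       xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Write a boundary curve as a plain-text vertex file
#'
#' One `x y label` line per point, preceded by `#`-comment header lines
#' recording the spacing and any geometry parameters.
#'
#' @param curve `boundary_curve`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vertex_file <- function(curve, path) {
  hdr <- c(sprintf("# trabflow vertex file: %d points", nrow(curve$points)),
           sprintf("# ds %.8g", curve$ds))
  if (!is.null(curve$params)) {
    pl <- curve$params
    nm <- names(pl)[vapply(pl, is.numeric, TRUE)]
    hdr <- c(hdr, sprintf("# %s %.8g", nm, unlist(pl[nm])))
  }
  lines <- sprintf("%.10g %.10g %s", curve$points[, 1], curve$points[, 2],
                   curve$labels)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a boundary curve written by [write_vertex_file()]
#' @param path vertex file
#' @return `boundary_curve` (points, labels, spacing; normals recomputed
#'   are not available and set to NA)
#' @export
read_vertex_file <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  ds_line <- hdr[grepl("^# ds ", hdr)]
  ds <- if (length(ds_line)) as.numeric(sub("^# ds ", "", ds_line[1])) else NA
  parts <- strsplit(body, " ")
  pts <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  labs <- vapply(parts, function(p) paste(p[-(1:2)], collapse = " "), "")
  new_boundary_curve(pts, matrix(NA_real_, nrow(pts), 2), labs, ds)
}
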