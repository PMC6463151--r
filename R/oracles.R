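# Analytic flows and constructed stream-function fields: closed-form
# solutions of the governing equations used as independent oracles for the
# solver and the flow-analysis tools.

new_analytic_flow <- function(name, params, u, v, p, psi, nu, sample) {
  structure(list(name = name, params = params, u = u, v = v, p = p,
                 psi = psi, nu = nu, sample = sample),
            class = "analytic_flow")
}

#' @export
print.analytic_flow <- function(x, ...) {
  cat("Analytic flow:", x$name, "\n")
  str(x$params, give.attr = FALSE)
  invisible(x)
}

#' @importFrom utils str
NULL

#' Plane Poiseuille channel flow
#'
#' Steady pressure-driven flow between walls at `y0` and `y0 + width`:
#' parabolic profile, zero at the walls, `Vmax` at the centerline.  The
#' analytic wall shear stress is `4 mu Vmax / width`.
#'
#' @param width channel width
#' @param Vmax centerline speed
#' @param y0 lower wall position, default 0
#' @param mu dynamic viscosity, default 1
#' @return `analytic_flow` with evaluators `u(x, y, t)`, `v`, `p`, `psi`
#'   and element `wall_shear`
#' @export
make_poiseuille <- function(width, Vmax, y0 = 0, mu = 1) {
  if (width <= 0) stop("width must be positive")
  w <- width
  inside <- function(y) y >= y0 & y <= y0 + w
  fl <- new_analytic_flow(
    "poiseuille", list(width = w, Vmax = Vmax, y0 = y0, mu = mu),
    u = function(x, y, t = 0) ifelse(inside(y), 4 * Vmax * (y - y0) * (y0 + w - y) / w^2, 0),
    v = function(x, y, t = 0) 0 * x,
    p = function(x, y, t = 0) -8 * mu * Vmax / w^2 * x,
    psi = function(x, y, t = 0) {
      d <- pmin(pmax(y - y0, 0), w)
      4 * Vmax / w^2 * (w * d^2 / 2 - d^3 / 3)
    },
    nu = mu,
    sample = function(n) {
      yy <- y0 + w * seq(0.05, 0.95, length.out = n)
      list(x = seq(0, 1, length.out = n), y = yy)
    })
  fl$wall_shear <- 4 * mu * Vmax / w
  fl
}

#' Decaying Taylor-Green vortex array
#'
#' Exact unsteady Navier-Stokes solution on a periodic domain:
#' `u = A cos(kx) sin(ky) F(t)`, `v = -A sin(kx) cos(ky) F(t)` with
#' `F = exp(-2 nu k^2 t)`; the kinetic energy decays as
#' `exp(-4 nu k^2 t)`.
#'
#' @param k wavenumber (use `2 pi m / L` for periodic compatibility)
#' @param amplitude velocity amplitude `A`
#' @param nu kinematic viscosity
#' @return `analytic_flow`; element `energy(t, Lx, Ly)` gives the total
#'   kinetic energy `A^2 F^2 Lx Ly / 4`
#' @export
make_taylor_green <- function(k, amplitude, nu) {
  A <- amplitude
  Fd <- function(t) exp(-2 * nu * k^2 * t)
  fl <- new_analytic_flow(
    "taylor_green", list(k = k, amplitude = A, nu = nu),
    u = function(x, y, t = 0) A * cos(k * x) * sin(k * y) * Fd(t),
    v = function(x, y, t = 0) -A * sin(k * x) * cos(k * y) * Fd(t),
    p = function(x, y, t = 0) -(A^2 * Fd(t)^2 / 4) * (cos(2 * k * x) + cos(2 * k * y)),
    psi = function(x, y, t = 0) (A / k) * cos(k * x) * cos(k * y) * Fd(t),
    nu = nu,
    sample = function(n) list(x = seq(0, 2 * pi / k, length.out = n),
                              y = seq(0, 2 * pi / k, length.out = n)))
  fl$energy <- function(t, Lx, Ly) A^2 * Fd(t)^2 * Lx * Ly / 4
  fl
}

#' Solid-body rotation patch
#'
#' Rigid rotation at angular velocity `Omega` inside radius `R` about
#' `center` (quiescent outside): `psi = -Omega r^2 / 2` inside the patch,
#' with a single interior extremum at the rotation center.  Positive
#' `Omega` is counter-clockwise.
#'
#' @param center 2-vector
#' @param Omega angular velocity
#' @param R patch radius
#' @return `analytic_flow`
#' @export
make_solid_rotation <- function(center, Omega, R) {
  r2 <- function(x, y) (x - center[1])^2 + (y - center[2])^2
  new_analytic_flow(
    "solid_rotation", list(center = center, Omega = Omega, R = R),
    u = function(x, y, t = 0) ifelse(r2(x, y) < R^2, -Omega * (y - center[2]), 0),
    v = function(x, y, t = 0) ifelse(r2(x, y) < R^2, Omega * (x - center[1]), 0),
    p = function(x, y, t = 0) ifelse(r2(x, y) < R^2, Omega^2 * r2(x, y) / 2, Omega^2 * R^2 / 2),
    psi = function(x, y, t = 0) ifelse(r2(x, y) < R^2, -Omega * r2(x, y) / 2, -Omega * R^2 / 2),
    nu = 0,
    sample = function(n) {
      s <- seq(-0.6 * R, 0.6 * R, length.out = n)
      list(x = center[1] + s, y = center[2] + s)
    })
}

#' Uniform flow
#' @param cu,cv constant velocity components
#' @return `analytic_flow` with `psi = cu y - cv x`
#' @export
make_uniform <- function(cu, cv = 0) {
  new_analytic_flow(
    "uniform", list(cu = cu, cv = cv),
    u = function(x, y, t = 0) rep(cu, length(x)),
    v = function(x, y, t = 0) rep(cv, length(x)),
    p = function(x, y, t = 0) rep(0, length(x)),
    psi = function(x, y, t = 0) cu * y - cv * x,
    nu = 0,
    sample = function(n) list(x = seq(0, 1, length.out = n),
                              y = seq(0, 1, length.out = n)))
}

#' Evaluate an analytic flow on a grid
#' @param flow `analytic_flow`
#' @param grid `fluid_grid`
#' @param t time, default 0
#' @return `fluid_state` with the sampled `u`, `v`, `p`
#' @export
evaluate_flow <- function(flow, grid, t = 0) {
  X <- matrix(rep(grid$x, grid$Ny), grid$Nx, grid$Ny)
  Y <- matrix(rep(grid$y, each = grid$Nx), grid$Nx, grid$Ny)
  new_fluid_state(matrix(flow$u(X, Y, t), grid$Nx, grid$Ny),
                  matrix(flow$v(X, Y, t), grid$Nx, grid$Ny),
                  matrix(flow$p(X, Y, t), grid$Nx, grid$Ny),
                  t, grid)
}

#' Self-audit: PDE residual of an analytic flow
#'
#' Evaluates the continuity and momentum residuals of the closed-form
#' evaluators on an `n x n` interior sample (away from patch edges and
#' walls where the fields are only piecewise smooth), using five-point
#' finite differences with a small step on the analytic functions, so
#' polynomial/trigonometric fields are differentiated to near round-off.
#'
#' @param flow `analytic_flow`
#' @param n sample size per direction, default 64
#' @param t time, default 0
#' @param fd_h differencing step, default 1e-3
#' @return named vector: max abs continuity and momentum residuals
#' @export
flow_residual <- function(flow, n = 64, t = 0, fd_h = 1e-3) {
  s <- flow$sample(n)
  X <- matrix(rep(s$x, n), n, n)
  Y <- matrix(rep(s$y, each = n), n, n)
  d1 <- function(f, wrt) {
    h <- fd_h
    if (wrt == "x")
      (-f(X + 2 * h, Y, t) + 8 * f(X + h, Y, t) - 8 * f(X - h, Y, t) + f(X - 2 * h, Y, t)) / (12 * h)
    else
      (-f(X, Y + 2 * h, t) + 8 * f(X, Y + h, t) - 8 * f(X, Y - h, t) + f(X, Y - 2 * h, t)) / (12 * h)
  }
  d2 <- function(f, wrt) {
    h <- fd_h
    if (wrt == "x")
      (-f(X + 2 * h, Y, t) + 16 * f(X + h, Y, t) - 30 * f(X, Y, t) + 16 * f(X - h, Y, t) - f(X - 2 * h, Y, t)) / (12 * h^2)
    else
      (-f(X, Y + 2 * h, t) + 16 * f(X, Y + h, t) - 30 * f(X, Y, t) + 16 * f(X, Y - h, t) - f(X, Y - 2 * h, t)) / (12 * h^2)
  }
  dt1 <- function(f) {
    h <- fd_h
    (-f(X, Y, t + 2 * h) + 8 * f(X, Y, t + h) - 8 * f(X, Y, t - h) + f(X, Y, t - 2 * h)) / (12 * h)
  }
  u <- flow$u(X, Y, t); v <- flow$v(X, Y, t)
  cont <- d1(flow$u, "x") + d1(flow$v, "y")
  mom_x <- dt1(flow$u) + u * d1(flow$u, "x") + v * d1(flow$u, "y") +
    d1(flow$p, "x") - flow$nu * (d2(flow$u, "x") + d2(flow$u, "y"))
  mom_y <- dt1(flow$v) + u * d1(flow$v, "x") + v * d1(flow$v, "y") +
    d1(flow$p, "y") - flow$nu * (d2(flow$v, "x") + d2(flow$v, "y"))
  c(continuity = max(abs(cont)), momentum = max(abs(mom_x), abs(mom_y)))
}

#' Constructed stream-function field with known vortices
#'
#' Sum of Gaussian `psi` bumps with known centers, signs and widths:
#' ground truth for the closed-streamline vortex detector.  Supports must
#' not overlap (center separation of at least 3 times the summed widths).
#'
#' @param centers m x 2 matrix of bump centers
#' @param amplitudes signed amplitudes (positive = counter-clockwise)
#' @param sigmas Gaussian widths
#' @param grid `fluid_grid` to evaluate on
#' @param detect_frac bumps with `|amplitude|` below this fraction of the
#'   largest are excluded from the ground truth (they fall below a
#'   matching detector depth threshold), default 0
#' @return list: `psi` matrix, `field` (`stream_function_field`),
#'   `truth` data frame (`x`, `y`, `sense`)
#' @export
make_constructed_psi <- function(centers, amplitudes, sigmas, grid,
                                 detect_frac = 0) {
  centers <- matrix(centers, ncol = 2)
  m <- nrow(centers)
  stopifnot(length(amplitudes) == m, length(sigmas) == m)
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (d < 3 * (sigmas[i] + sigmas[j]))
        stop("overlapping vortex supports in constructed psi field")
    }
  }
  X <- matrix(rep(grid$x, grid$Ny), grid$Nx, grid$Ny)
  Y <- matrix(rep(grid$y, each = grid$Nx), grid$Nx, grid$Ny)
  psi <- matrix(0, grid$Nx, grid$Ny)
  for (k in seq_len(m)) {
    r2 <- (X - centers[k, 1])^2 + (Y - centers[k, 2])^2
    psi <- psi + amplitudes[k] * exp(-r2 / (2 * sigmas[k]^2))
  }
  amax <- if (m) max(abs(amplitudes)) else 1
  kept <- if (m) abs(amplitudes) >= detect_frac * amax else logical(0)
  truth <- data.frame(x = centers[kept, 1], y = centers[kept, 2],
                      sense = ifelse(amplitudes[kept] > 0, "ccw", "cw"))
  field <- structure(list(psi = psi, grid = grid, gauge = 0),
                     class = "stream_function_field")
  list(psi = psi, field = field, truth = truth)
}
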