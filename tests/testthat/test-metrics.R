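# Stream function, vortex detection, transects, WSS, TAWSS/OSI.

test_that("stream function reproduces closed forms", {
  g <- fluid_grid(64, 64, 3.2, 3.2)
  # uniform flow: psi = c y + const
  st <- evaluate_flow(make_uniform(2.5), g)
  sf <- stream_function(st)
  dpsi <- sf$psi - outer(rep(1, g$Nx), 2.5 * g$y)
  expect_lt(diff(range(dpsi)), 1e-8)
  # zero field: constant psi
  st0 <- evaluate_flow(make_uniform(0), g)
  expect_lt(diff(range(stream_function(st0)$psi)), 1e-12)
  # non-divergence-free input is rejected
  bad <- st
  bad$u <- matrix(rep(g$x, g$Ny), g$Nx, g$Ny)  # du/dx = 1
  expect_error(stream_function(bad), "divergence")
})

test_that("psi derivatives reconstruct the velocity field (O(h^2))", {
  k <- 2 * pi / 3.2
  tg <- make_taylor_green(k = k, amplitude = 1, nu = 0.05)
  errs <- sapply(c(32, 64), function(n) {
    g <- fluid_grid(n, n, 3.2, 3.2)
    st <- evaluate_flow(tg, g)
    psi <- stream_function(st)$psi
    dy <- (psi[, c(2:n, 1)] - psi[, c(n, 1:(n - 1))]) / (2 * g$h)
    max(abs(dy - st$u))
  })
  expect_lt(errs[2], errs[1] / 3)   # ~4x per refinement
  expect_lt(errs[2], 5e-3)
})

test_that("solid-rotation patch yields one interior extremum vortex", {
  g <- fluid_grid(64, 64, 3.2, 3.2)
  sr <- make_solid_rotation(center = c(1.6, 1.6), Omega = 1.5, R = 0.5)
  X <- matrix(rep(g$x, g$Ny), g$Nx, g$Ny)
  Y <- matrix(rep(g$y, each = g$Nx), g$Nx, g$Ny)
  fld <- structure(list(psi = matrix(sr$psi(X, Y), g$Nx, g$Ny), grid = g,
                        gauge = 0), class = "stream_function_field")
  vr <- detect_vortices(fld)
  expect_equal(nrow(vr), 1)
  expect_equal(vr$x, 1.6, tolerance = 2 * g$h)
  expect_equal(vr$y, 1.6, tolerance = 2 * g$h)
  expect_equal(vr$sense, "ccw")  # psi maximum at the center: Omega > 0 is ccw
})

test_that("vortex detector recovers constructed ground truth exactly", {
  g <- fluid_grid(64, 64, 3.2, 3.2)
  # peak widths of a few cells: the closedness contour near an extremum
  # must be resolvable on the grid (sub-cell peaks are below the
  # detector's resolution floor by design)
  cp <- make_constructed_psi(rbind(c(1, 1), c(2.4, 2.2)), c(0.02, -0.03),
                             c(0.22, 0.2), g)
  vr <- detect_vortices(cp$field)
  expect_equal(nrow(vr), 2)
  ord <- order(vr$x)
  expect_equal(vr$x[ord], cp$truth$x, tolerance = 2 * g$h)
  expect_equal(vr$y[ord], cp$truth$y, tolerance = 2 * g$h)
  expect_equal(vr$sense[ord], cp$truth$sense)
  # a bump below the depth threshold is not reported
  cp2 <- make_constructed_psi(rbind(c(1, 1), c(2.4, 2.2)), c(0.02, -1e-7),
                              c(0.22, 0.2), g)
  vr2 <- detect_vortices(cp2$field)
  expect_equal(nrow(vr2), 1)
  expect_equal(vr2$sense, "ccw")
  # empty field: empty report is valid
  cp0 <- make_constructed_psi(matrix(numeric(0), 0, 2), numeric(0),
                              numeric(0), g)
  expect_equal(nrow(detect_vortices(cp0$field)), 0)
})

test_that("vortex detection agrees with RK4 particle tracing", {
  g <- fluid_grid(64, 64, 3.2, 3.2)
  cp <- make_constructed_psi(rbind(c(1.2, 1.4)), 0.05, 0.25, g)
  # build the velocity field from psi: u = dpsi/dy, v = -dpsi/dx
  n <- g$Nx
  u <- (cp$psi[, c(2:n, 1)] - cp$psi[, c(n, 1:(n - 1))]) / (2 * g$h)
  v <- -(cp$psi[c(2:n, 1), ] - cp$psi[c(n, 1:(n - 1)), ]) / (2 * g$h)
  st <- structure(list(u = u, v = v, grid = g), class = "fluid_state")
  vr <- detect_vortices(cp$field)
  expect_equal(nrow(vr), 1)
  # a particle seeded inside the detected vortex returns near its start
  start <- c(vr$x + 0.1, vr$y)
  path <- trace_streamline(st, start, dt = 0.5, nsteps = 2000)
  d_start <- sqrt(rowSums((path - matrix(start, 2001, 2, byrow = TRUE))^2))
  # it must come back within a cell after leaving
  away <- which(d_start > 3 * g$h)
  expect_true(length(away) > 0)
  expect_lt(min(d_start[-(1:min(away))]), 1.5 * g$h)
})

test_that("transects reproduce closed-form profiles and reject bad input", {
  g <- test_grid()
  fl <- make_poiseuille(width = 0.8, Vmax = 1, y0 = 0.8)
  st <- evaluate_flow(fl, g)
  tr <- velocity_transect(st, c(3.2, 0.8), c(3.2, 1.6), n = 129)
  expect_equal(nrow(tr), 129)
  ana <- fl$u(tr$x, tr$y)
  expect_lt(max(abs(tr$speed - ana)), 0.03)   # within 3% of Vmax
  # quiescent region: zeros
  tr0 <- velocity_transect(st, c(3.2, 2.0), c(3.2, 3.0))
  expect_equal(max(tr0$speed), 0)
  expect_error(velocity_transect(st, c(-1, 0), c(1, 1)), "outside")
})

test_that("WSS recovers the Poiseuille wall shear within 5%", {
  g <- test_grid()
  gp <- geometry_params()
  ch <- build_channel(gp, g$h)
  mu <- 0.4
  fl <- make_poiseuille(width = 0.8, Vmax = 1, y0 = 0.8, mu = mu)
  st <- evaluate_flow(fl, g)
  st$flow <- list(nu = mu)
  wss <- wall_shear_stress(st, ch)
  mag <- sqrt(rowSums(wss^2))
  expect_equal(mean(mag), fl$wall_shear, tolerance = 0.05)
  # quiescent fluid: zero WSS
  st0 <- evaluate_flow(make_uniform(0), g)
  st0$flow <- list(nu = mu)
  expect_equal(max(abs(wall_shear_stress(st0, ch))), 0)
})

test_that("TAWSS/OSI limits: aligned 0, reversing 0.5, quadrature case", {
  n <- 5
  mk <- function(f) lapply(seq(0.125, 1, by = 0.125),
                           function(fr) matrix(f(fr), n, 2))
  tms <- seq(0.125, 1, by = 0.125)
  # constant-direction WSS: OSI = 0
  sh1 <- list(times = tms, wss = mk(function(fr) c(rep(1, n), rep(0, n))))
  r1 <- tawss_osi(sh1)
  expect_equal(r1$osi, rep(0, n))
  expect_equal(r1$tawss, rep(1, n))
  # sign-reversing equal halves: OSI = 0.5
  sh2 <- list(times = tms,
              wss = mk(function(fr) c(rep(ifelse(fr <= 0.5, 1, -1), n),
                                      rep(0, n))))
  expect_equal(tawss_osi(sh2)$osi, rep(0.5, n), tolerance = 1e-12)
  # rotating WSS over a quarter circle: OSI from direct quadrature
  m <- 64
  tq <- seq(1 / m, 1, by = 1 / m)
  th <- (pi / 2) * tq
  shq <- list(times = tq,
              wss = lapply(th, function(a) matrix(c(cos(a), sin(a)), 1, 2)))
  got <- tawss_osi(shq)$osi
  # quadrature oracle: |mean vector| / mean |vector| for unit vectors
  mean_vec <- c(mean(cos(th)), mean(sin(th)))
  osi_expected <- 0.5 * (1 - sqrt(sum(mean_vec^2)))
  expect_equal(got, osi_expected, tolerance = 1e-10)
  # zero-shear points have OSI defined as 0
  sh0 <- list(times = tms, wss = mk(function(fr) rep(0, 2 * n)))
  expect_equal(tawss_osi(sh0)$osi, rep(0, n))
})

test_that("OSI is bounded in [0, 0.5] for arbitrary shear histories", {
  set.seed(99)
  for (rep in 1:20) {
    m <- sample(4:12, 1)
    sh <- list(times = seq(1 / m, 1, by = 1 / m),
               wss = replicate(m, matrix(rnorm(20), 10, 2), simplify = FALSE))
    osi <- tawss_osi(sh)$osi
    expect_true(all(osi >= 0 - 1e-12 & osi <= 0.5 + 1e-12))
  }
})

test_that("region averages obey the weighted-mean identity", {
  cv <- cached_chamber(0.08)
  n <- nrow(cv$points)
  # uniform field: every region returns the same value
  u <- rep(3, n)
  for (reg in c("trabecula", "intertrabecular", "channel-wall", "ventricle"))
    expect_equal(region_average(u, cv, reg), 3)
  # single nonzero point contributes by its (uniform) arc-length weight
  i1 <- which(cv$labels == "trabecula[2]")[1]
  z <- rep(0, n); z[i1] <- 7
  n2 <- sum(cv$labels == "trabecula[2]")
  expect_equal(region_average(z, cv, "trabecula[2]"), 7 / n2)
  # whole-lining mean equals the point-count-weighted combination of the
  # sub-region means (uniform spacing => arc-length weights)
  set.seed(1)
  vals <- runif(n)
  regs <- c(sprintf("trabecula[%d]", 1:6), sprintf("intertrabecular[%d]", 0:6))
  parts <- sapply(regs, function(r) region_average(vals, cv, r))
  wts <- sapply(regs, function(r) sum(cv$labels == r))
  expect_equal(region_average(vals, cv, "ventricle"),
               sum(parts * wts) / sum(wts))
  expect_error(region_average(u, cv, "no-such-region"), "empty")
})
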