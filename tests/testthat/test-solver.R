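# Navier-Stokes core: closed-form validation and solver invariants.

test_that("zero forcing leaves a quiescent field unchanged", {
  g <- coarse_grid()
  st <- new_state <- ns_step(list(u = matrix(0, g$Nx, g$Ny),
                                  v = matrix(0, g$Nx, g$Ny)),
                             g, nu = 0.1, dt = 1e-3, nsteps = 10)
  expect_equal(max(abs(new_state$u)), 0)
  expect_equal(max(abs(new_state$v)), 0)
})

test_that("Taylor-Green energy decays as the closed form within 1%", {
  k <- 2 * pi / 3.2
  nu <- 0.05
  tg <- make_taylor_green(k = k, amplitude = 1, nu = nu)
  g <- fluid_grid(64, 64, 3.2, 3.2)
  st <- evaluate_flow(tg, g)
  # integrate over one viscous time 1/(2 nu k^2)
  t_visc <- 1 / (2 * nu * k^2)
  dt <- 2e-3
  n <- round(t_visc / dt)
  st1 <- ns_step(st, g, nu = nu, dt = dt, nsteps = n)
  ratio <- sum(st1$u^2 + st1$v^2) / sum(st$u^2 + st$v^2)
  expect_equal(ratio, exp(-4 * nu * k^2 * n * dt), tolerance = 0.01)
  # pointwise the solution stays a pure Taylor-Green mode
  ana <- evaluate_flow(tg, g, t = n * dt)
  expect_lt(max(abs(st1$u - ana$u)), 0.01)
})

test_that("discrete divergence vanishes after every projection", {
  g <- coarse_grid()
  set.seed(3)
  st <- list(u = matrix(rnorm(g$Nx * g$Ny), g$Nx, g$Ny),
             v = matrix(rnorm(g$Nx * g$Ny), g$Nx, g$Ny))
  st1 <- ns_step(st, g, nu = 0.01, dt = 1e-3, nsteps = 1)
  div <- trabflow:::ddx(st1$u, g$h) + trabflow:::ddy(st1$v, g$h)
  expect_lt(max(abs(div)), 1e-10)
  # and after several steps of nonlinear evolution
  st5 <- ns_step(st1, g, nu = 0.01, dt = 1e-3, nsteps = 5)
  div5 <- trabflow:::ddx(st5$u, g$h) + trabflow:::ddy(st5$v, g$h)
  expect_lt(max(abs(div5)), 1e-10)
})

test_that("driven channel converges to Poiseuille flow within 3%", {
  g <- test_grid()
  ch <- build_channel(geometry_params(), g$h)
  fl <- flow_params(Re = 1, mode = "steady")
  st <- cached("poiseuille_128", {
    suppressWarnings(run_steady(ch, fl, g, ib_params(t_max = 30),
                                on_nonconvergence = "warn"))
  })
  lay <- ch$layout
  ix <- which.min(abs(g$x - 4.8))       # far from band and walls
  yin <- g$y > lay$y_bot + g$h & g$y < lay$y_top - g$h
  ana <- 4 * (g$y - lay$y_bot) * (lay$y_top - g$y) / 0.8^2
  err <- max(abs(st$u[ix, yin] - ana[yin]))
  expect_lt(err, 0.03)                   # 3% of the unit centerline speed
  expect_lt(abs(max(st$u[ix, ]) - 1), 0.03)
  # simulated wall shear within 5% of 4 mu Vmax / w
  wss <- wall_shear_stress(st, ch)
  mid <- ch$target[, 1] > 4 & ch$target[, 1] < 5.6
  expect_equal(mean(sqrt(rowSums(wss[mid, ]^2))),
               4 * fl$nu * 1 / 0.8, tolerance = 0.05)
})

test_that("Stokes regime: doubling the inflow doubles the whole field", {
  g <- coarse_grid()
  cv <- build_channel(geometry_params(), g$h)
  run_v <- function(Vin) {
    fl <- flow_params(Re = 0.01, mode = "steady", Vin = Vin)
    suppressWarnings(run_steady(cv, fl, g, ib_params(t_max = 10),
                                on_nonconvergence = "warn"))
  }
  s1 <- cached("stokes_v1", run_v(1))
  s2 <- cached("stokes_v2", run_v(2))
  # compare on the resolved flow region: inside the channel, clear of
  # the kernel-smeared wall layers and downstream of the driving band
  X <- matrix(rep(g$x, g$Ny), g$Nx, g$Ny)
  Y <- matrix(rep(g$y, each = g$Nx), g$Nx, g$Ny)
  sel <- abs(s1$u) > 0.05 & X > 2 & Y > 0.9 & Y < 1.5
  expect_lt(max(abs(s2$u[sel] / s1$u[sel] - 2)), 0.02)
})

test_that("Stokes flow over the cavity is fore-aft symmetric", {
  g <- test_grid()
  cv <- cached_chamber(0)
  st <- cached_steady(0.01, 0)
  # |u| in the cavity mirrored about the cavity midline x = xc
  lay <- cv$layout
  masks <- cached_masks(0)
  sp <- sqrt(st$u^2 + st$v^2)
  # compare on the cavity interior (the kernel-smeared wall ring carries
  # flow-directional tether adjustments that are not part of the
  # resolved Stokes field)
  ic <- which(masks$cavity & masks$interior, arr.ind = TRUE)
  keep <- ic[, 1] > 1
  ic <- ic[keep, , drop = FALSE]
  xm <- 2 * lay$xc - g$x[ic[, 1]]
  im <- round(xm / g$h) + 1
  ok <- im >= 1 & im <= g$Nx
  a <- sp[ic[ok, , drop = FALSE]]
  b <- sp[cbind(im[ok], ic[ok, 2])]
  expect_lt(max(abs(a - b)) / max(sp[masks$cavity]), 0.05)
})

test_that("halving the grid spacing changes the centerline speed < 5%", {
  coarse <- cached("refine_64", {
    g <- coarse_grid()
    cv <- build_idealized_chamber(geometry_params(hT = 0), g$h)
    st <- suppressWarnings(run_steady(cv, flow_params(1, "steady"), g,
                                      ib_params(t_max = 30),
                                      on_nonconvergence = "warn"))
    list(st = st, g = g, cv = cv)
  })
  fine <- cached("steady_1_0_128", cached_steady(1, 0))
  probe <- function(st, g, cv) {
    lay <- cv$layout
    bilinear_probe <- velocity_transect(st, c(lay$xc, lay$y_bot + 0.1),
                                        c(lay$xc, lay$y_top - 0.1), n = 33)
    max(bilinear_probe$speed)
  }
  v_coarse <- probe(coarse$st, coarse$g, coarse$cv)
  v_fine <- probe(fine, test_grid(), cached_chamber(0))
  expect_lt(abs(v_fine - v_coarse) / v_fine, 0.05)
})

test_that("pulsatile runs respect phases, rigidity and quiescent limits", {
  pr <- cached_pulsatile(1, 0.08)
  fl <- pr$flow
  # snapshot times hit the requested cycle fractions within dt
  t_expect <- (fl$n_cycles - 1 + pr$phases) * fl$T
  t_got <- vapply(pr$snapshots, function(s) s$t, 0)
  expect_lt(max(abs(t_got - t_expect)), 0.01 * fl$T)
  # boundary deviation below 1% of the chamber diameter
  expect_lt(pr$max_deviation, 0.01 * 2 * 1.0)
  # near-zero inflow at the cycle boundary: flow much weaker than
  # mid-cycle
  sp_end <- max(sqrt(pr$snapshots[[9]]$u^2 + pr$snapshots[[9]]$v^2))
  sp_mid <- max(sqrt(pr$snapshots[[5]]$u^2 + pr$snapshots[[5]]$v^2))
  expect_lt(sp_end, 0.5 * sp_mid)
})

test_that("zero inflow amplitude gives identically zero flow", {
  g <- coarse_grid()
  cv <- build_idealized_chamber(geometry_params(hT = 0), g$h)
  fl <- flow_params(Re = 1, mode = "pulsatile", Vin = 0, n_cycles = 2)
  fl$Vin <- 0
  pr <- suppressWarnings(run_pulsatile(cv, fl, g,
                                       ib_params(k_tether = 50000)))
  expect_lt(max(abs(pr$snapshots[[5]]$u)), 1e-12)
})
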