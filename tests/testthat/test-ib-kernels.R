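# Regularized-delta spreading / interpolation and tether forces.

test_that("force spreading conserves total force and has compact support", {
  g <- coarse_grid()
  ds <- 0.5 * g$h
  p <- matrix(c(1.513, 0.781), 1, 2)
  zero <- spread_force(p, matrix(0, 1, 2), g, ds)
  expect_equal(max(abs(zero$fx)), 0)
  sp <- spread_force(p, matrix(c(1, 0), 1, 2), g, ds)
  # total Eulerian force (sum * h^2) equals Lagrangian (1 * ds)
  expect_equal(sum(sp$fx) * g$h^2, ds, tolerance = 1e-12)
  expect_equal(sum(sp$fy), 0)
  # support is 4x4 cells
  expect_lte(sum(sp$fx != 0), 16)
  # translation by a full cell translates the field exactly
  sp2 <- spread_force(p + g$h, matrix(c(1, 0), 1, 2), g, ds)
  expect_equal(sp2$fx[2:g$Nx, 2:g$Ny], sp$fx[1:(g$Nx - 1), 1:(g$Ny - 1)])
  expect_error(spread_force(matrix(c(-1, 0), 1, 2), matrix(1, 1, 2), g, ds),
               "outside")
})

test_that("velocity interpolation is exact for uniform and O(h^2) for shear", {
  g <- coarse_grid()
  p <- cbind(runif(20, 1, 5), runif(20, 1, 2.5))
  state <- list(u = matrix(3.7, g$Nx, g$Ny), v = matrix(-1.2, g$Nx, g$Ny))
  uv <- interpolate_velocity(state, p, g)
  expect_equal(uv[, 1], rep(3.7, 20), tolerance = 1e-12)
  expect_equal(uv[, 2], rep(-1.2, 20), tolerance = 1e-12)
  expect_equal(interpolate_velocity(list(u = 0 * state$u, v = 0 * state$v),
                                    p, g), matrix(0, 20, 2))
  # linear shear u = y interpolates with O(h^2) error, refining 4x per
  # halving
  errs <- sapply(list(coarse_grid(), test_grid()), function(gg) {
    Y <- matrix(rep(gg$y, each = gg$Nx), gg$Nx, gg$Ny)
    st <- list(u = Y, v = 0 * Y)
    pp <- cbind(seq(1, 5, length.out = 11), seq(1.1, 2.3, length.out = 11))
    max(abs(interpolate_velocity(st, pp, gg)[, 1] - pp[, 2]))
  })
  expect_lt(errs[2], errs[1])   # second-order moment error shrinks with h
})

test_that("spreading and interpolation are adjoint to round-off", {
  g <- coarse_grid()
  ds <- 0.5 * g$h
  set.seed(11)
  for (rep in 1:3) {
    p <- cbind(runif(15, 0.5, 5.5), runif(15, 0.5, 2.7))
    FF <- matrix(rnorm(30), 15, 2)
    U <- matrix(rnorm(g$Nx * g$Ny), g$Nx, g$Ny)
    V <- matrix(rnorm(g$Nx * g$Ny), g$Nx, g$Ny)
    sp <- spread_force(p, FF, g, ds)
    iv <- interpolate_velocity(list(u = U, v = V), p, g)
    lhs <- sum(sp$fx * U + sp$fy * V) * g$h^2
    rhs <- sum(FF[, 1] * iv[, 1] + FF[, 2] * iv[, 2]) * ds
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("tether forces are linear restoring forces", {
  tgt <- cbind(1:4, 4:1)
  expect_equal(tether_forces(tgt, tgt, 50), matrix(0, 4, 2))
  d <- cbind(c(0.1, 0, -0.2, 0), c(0, 0.3, 0, -0.1))
  f <- tether_forces(tgt + d, tgt, 50)
  expect_equal(f, -50 * d)
  expect_error(tether_forces(tgt[1:3, ], tgt, 50), "matching")
})

test_that("doubling tether stiffness halves the static deviation", {
  # static balance: constant load F on a tethered point gives d = F/K
  g <- coarse_grid()
  dev_for_K <- function(K) {
    cv <- build_channel(geometry_params(), g$h)
    fl <- flow_params(Re = 5, mode = "steady")
    st <- suppressWarnings(run_steady(cv, fl, g,
                                      ib_params(k_tether = K, t_max = 6,
                                                df_iters = 0),
                                      on_nonconvergence = "warn"))
    st$max_deviation
  }
  d1 <- dev_for_K(2000)
  d2 <- dev_for_K(4000)
  expect_equal(d1 / d2, 2, tolerance = 0.35)
})

test_that("inflow gain follows the ramp and sin^2 waveforms", {
  fls <- flow_params(Re = 1, mode = "steady", ramp_tau = 0.5)
  expect_equal(inflow_velocity(0, fls), 0)
  expect_equal(inflow_velocity(0.25, fls), 0.5)      # half-way up the ramp
  expect_equal(inflow_velocity(10, fls), 1)
  flp <- flow_params(Re = 1, mode = "pulsatile")
  T <- flp$T
  expect_equal(inflow_velocity(0, flp), 0)            # cycle start: no flow
  expect_equal(inflow_velocity(T, flp), 0, tolerance = 1e-12)
  expect_equal(inflow_velocity(T / 2, flp), 1)        # mid-cycle maximum
  # time-mean of the gain over one period is Vin / 2
  tt <- seq(0, T, length.out = 2001)
  expect_equal(mean(inflow_velocity(tt, flp)), 0.5, tolerance = 1e-3)
  # parabolic profile: zero at walls, Vin at the centerline
  y <- c(0.8, 1.2, 1.6)
  prof <- inflow_velocity(T / 2, flp, y = y)
  expect_equal(as.numeric(prof), c(0, 1, 0))
})

test_that("flow parameters derive viscosity and period per definitions", {
  fs <- flow_params(Re = 2, mode = "steady")
  expect_equal(fs$nu, 1 * 0.8 / 2)
  fp <- flow_params(Re = 2, mode = "pulsatile", f_nd = 0.1)
  expect_equal(fp$Vchar, 0.5)
  expect_equal(fp$nu, 0.5 * 0.8 / 2)
  expect_equal(fp$T, 0.8 / (0.1 * 0.5))
  expect_error(flow_params(Re = 0), "Re")
})
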