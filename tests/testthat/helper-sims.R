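# Shared simulation cache: several test files interrogate the same
# steady/pulsatile solutions, so runs are memoised for the session.

.sim_cache <- new.env(parent = emptyenv())

trabflow_test_env <- function() .sim_cache

test_grid <- function() fluid_grid(128, 64)
coarse_grid <- function() fluid_grid(64, 32)

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_chamber <- function(hT_bV, grid = test_grid()) {
  cached(sprintf("curve_%g_%d", hT_bV, grid$Nx), {
    build_idealized_chamber(geometry_params(hT = hT_bV * 0.8), grid$h)
  })
}

cached_masks <- function(hT_bV, grid = test_grid()) {
  cached(sprintf("masks_%g_%d", hT_bV, grid$Nx), {
    region_masks(cached_chamber(hT_bV, grid), grid)
  })
}

cached_steady <- function(Re, hT_bV, grid = test_grid()) {
  cached(sprintf("steady_%g_%g_%d", Re, hT_bV, grid$Nx), {
    curve <- cached_chamber(hT_bV, grid)
    flow <- flow_params(Re = Re, mode = "steady")
    # viscosity-dominated runs are steady within a few time units
    tm <- if (Re <= 0.1) 12 else 40
    suppressWarnings(run_steady(curve, flow, grid, ib_params(t_max = tm),
                                on_nonconvergence = "warn"))
  })
}

cached_pulsatile <- function(Re, hT_bV, grid = test_grid()) {
  cached(sprintf("puls_%g_%g_%d", Re, hT_bV, grid$Nx), {
    curve <- cached_chamber(hT_bV, grid)
    flow <- flow_params(Re = Re, mode = "pulsatile")
    suppressWarnings(run_pulsatile(curve, flow, grid, ib_params()))
  })
}

steady_vortices <- function(Re, hT_bV, grid = test_grid()) {
  cached(sprintf("vort_%g_%g_%d", Re, hT_bV, grid$Nx), {
    detect_vortices(cached_steady(Re, hT_bV, grid),
                    cached_chamber(hT_bV, grid),
                    cached_masks(hT_bV, grid))
  })
}
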