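Package: trabflow
Title: Immersed-Boundary Simulation of Flow in Trabeculated Embryonic Ventricles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional immersed-boundary simulations of incompressible
    flow through idealized and synthetic trabeculated embryonic ventricles,
    at the low Reynolds numbers (Re ~ 1) relevant to the onset of cardiac
    trabeculation in zebrafish. Provides parametric chamber geometries with
    Gaussian-like trabecular ridges, a tethered-boundary immersed-boundary
    Navier-Stokes solver with steady or pulsatile parabolic inflow, flow
    analysis tools (stream functions, closed-streamline vortex detection and
    classification, velocity transects, wall shear stress, TAWSS and the
    oscillatory shear index), and a sweep driver that maps vortex-formation
    bifurcations over Reynolds number, trabecula height and inflow mode.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
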