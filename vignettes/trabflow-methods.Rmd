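---
title: "Simulating intracardial flow in trabeculated embryonic ventricles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intracardial flow in trabeculated embryonic ventricles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trabflow)
```

## The scientific problem

At the onset of cardiac trabeculation in the zebrafish embryo (about
3--4 days post fertilization), the ventricle is a millimeter-scale
chamber in which inertial and viscous forces on the blood are nearly
balanced: with blood density 1025 kg/m^3, dynamic viscosity 0.0015
kg/(m s), a ventricle width of 208 um and a characteristic velocity of
0.75 cm/s, the Reynolds number is

```{r}
zebrafish_scales()   # Re ~ 1.07, dimensionless beat frequency ~ 0.11
```

At Re of order one, small changes in chamber shape, blood rheology or
flow unsteadiness can flip the topology of the intracardial flow --
whether closed recirculation (vortices) forms in the chamber or in the
grooves between the muscular ridges (trabeculae) lining the ventricle.
Because endocardial cells sense both the magnitude and the direction of
wall shear stress, such bifurcations are candidate epigenetic signals
for chamber and trabecular morphogenesis.

`trabflow` implements a two-dimensional immersed-boundary model of this
regime: an idealized trabeculated ventricle (a half-elliptical cavity
opening into a channel, with Gaussian-like ridges), a synthetic
generator of "realistic-like" ventricle outlines, an incompressible
Navier-Stokes solver with steady or pulsatile parabolic inflow, flow
analysis tools (stream functions, closed-streamline vortex detection,
velocity transects, WSS / TAWSS / OSI), and a sweep driver mapping
vortex-formation bifurcations over Reynolds number, trabecula height,
and inflow mode.

## Model geometry

The ventricle is idealized as a half ellipse (semi-axes `aV = 1.0`,
`bV = 0.8` in dimensionless units) laid tangentially into a channel of
width `wAV = 0.8` (the atrioventricular canal; the sinus-venosus width
is equal).  Six trabeculae of radius `rT = 0.10` and height `hT` are
placed at equal arc-length spacing along the elliptical wall, symmetric
about the cavity midline, each following the perturbed-Gaussian ridge
profile

  Trab(x) = hT (1 - (x/rT)^2) exp(-(x / 0.7 rT)^8),

applied along the local inward normal of the ellipse and clamped to
zero for |x| >= rT (ridges protrude into the chamber, never out of the
wall).  The biologically relevant relative height is `hT/bV = 0.08`;
the study range is 0 to 0.16.

```{r}
gp <- geometry_params(hT = 0.08 * 0.8)
grid <- fluid_grid(128, 64)
cv <- build_idealized_chamber(gp, grid$h)
plot(cv)
```

Every boundary point carries a region label (`channel-wall`,
`chamber-wall`, `trabecula[k]`, or `intertrabecular[k]`, where `k = 0`
and `k = n_trab` denote the flanking regions at the cavity edges), used
for vortex classification and regional WSS averages.

Because the traced outlines of real embryos are not published,
`build_synthetic_ventricle()` generates synthetic stand-ins: a periodic
smoothing spline through randomly perturbed control radii of an
elliptical base shape, with inward ridge-profile protrusions at
jittered angles and two angular gaps for the inflow and outflow.  The
construction is polar (star-shaped), which guarantees a
non-self-intersecting outline; outlines are reproducible for a fixed
seed.  These synthetic geometries emulate the qualitative features of
traced ventricles (ridge count, depth statistics, smoothness); they do
not reproduce any individual embryo, so results on them support
property-level statements (e.g. "valleys are shielded from shear"), not
embryo-specific comparisons.

## Fluid solver

The incompressible Navier-Stokes equations (unit density) are solved on
a doubly periodic rectangular grid (default 6.4 x 3.2, 128 x 64 nodes)
with a Fourier-based scheme: skew-symmetric central-difference
advection, semi-implicit (spectral) viscosity, and pressure projection
using the modified wavenumbers of the central difference operator, so
the discrete divergence vanishes to round-off after every step.  The
boundary couples to the grid through the standard 4-point cosine
regularized delta kernel: forces spread from the Lagrangian points to
the grid, velocities interpolate back with the adjoint operation, and
every point is tethered to its rest position by a stiff linear spring
(`F = -k (X - X_target)`), the standard immersed-boundary idiom for a
nearly rigid boundary.

Numerical choices that matter:

* **Tether stiffness** is auto-selected from a force-balance estimate
  (`k ~ 150 max(nu Vin / h, 3 Vin^2) / (0.01 * 2 aV)`) so that the
  maximum boundary displacement stays below 1% of the chamber diameter;
  every run verifies this contract and doubles the stiffness and reruns
  if it is violated.  [calibrate_tether()] provides an explicit
  pilot-run calibration.
* **Time step**: `dt = min(0.25 h / (1.6 Vin), h / sqrt(k ds))` -- the
  advective CFL bound and the tether-spring stability bound (the
  implicit viscous step damps spring oscillations well inside the
  explicit limit of `2h/sqrt(k ds)`).
* **Wall offset**: the regularized kernel places the hydrodynamically
  effective no-slip plane a fraction of a cell inside the Lagrangian
  points.  The solver therefore shifts the force points outward by
  0.3 h (calibrated once against plane Poiseuille flow, where the
  default recovers the parabolic profile to ~2.6%, the wall shear
  4 mu Vmax / w to ~2%, and a nominal-wall velocity below 1% of the
  centerline speed).  All analysis remains on the nominal geometry.
* **Inflow** is imposed by a penalty band spanning the channel upstream
  of the cavity that relaxes the local velocity toward the parabolic
  target profile; with the periodic domain the same band re-straightens
  the recirculating return flow.  Because the band must also supply the
  pressure drop of the whole periodic loop, its amplitude is adapted by
  a feedback controller until the measured centerline speed matches the
  nominal `Vin` (steady: after the startup ramp; pulsatile: around the
  mid-cycle peak, frozen after two cycles so the periodicity check is
  not confounded).  The fluid outside the channel-plus-chamber region
  is dynamically irrelevant and is weakly damped toward rest so it
  cannot spin up slowly through the slightly permeable smeared walls.
* **Steady convergence** is declared when the interior velocity (nodes
  more than 2.6 cells from the boundary, upstream of the cavity's
  downstream lip) changes by less than `3e-4 Vchar` per time unit.
  Two slow processes motivate this definition rather than a raw
  pointwise residual: the tether points keep settling toward their
  tangential force balance long after the measured flow is steady, and
  a low-level startup transient recirculates around the periodic
  channel.  Flow classifications are insensitive to residuals below
  ~1e-3.
* **Pulsatile runs** integrate 4 cycles of the `sin^2(pi t / T)`
  waveform (zero at cycle boundaries, maximal mid-cycle, time mean
  `Vin/2`, matching the pulsatile characteristic velocity) and declare
  periodic steady state when the cycle-to-cycle relative L2 velocity
  difference falls below 1%.

The scale definitions: `Re` uses the channel width `wAV` and the
characteristic velocity `Vin` (steady) or `Vin/2` (pulsatile); the Re
is varied through the kinematic viscosity.  The pulsatile dimensionless
frequency is fixed at 0.10, giving period `T = wAV / (0.1 Vchar)`.  The
Womersley number is reported as a diagnostic with the radius-based
definition `(wAV/2) sqrt(2 pi / (T nu))`; published values for this
system depend on the definition used, so no quantitative claim is
attached to it.

## Flow analysis

The stream function solves `lap(psi) = -omega` spectrally (plus the
mean-flow part), gauged to zero on the lower channel wall.  Vortices
are closed-streamline features: interior local extrema of psi around
which the contour at `psi_ext -/+ 0.05 * (gap to the wall streamline)`
closes entirely inside the fluid.  Contours enclosing less than one
grid cell of area are below the resolution floor and not reported.
Each vortex is classified by its center: inside an intertrabecular mask
(the valley within `hT + rT` of the wall between adjacent ridge crests)
it is intertrabecular, otherwise intracardial; a psi maximum rotates
counter-clockwise.  The detector is cross-checked against RK4 particle
tracing (a particle seeded inside a closed vortex returns near its
start) and against constructed stream-function fields with known
ground truth.

Wall shear stress is `mu du_t/dn` at each boundary point, with the
tangential velocity sampled at offsets 1.5h..3h along the inward normal
(outside the kernel core), a least-squares quadratic fit, and the
gradient evaluated at the fit's own zero crossing -- the effective wall.
For closed-form fields sampled analytically this estimator is exact;
on the driven-channel simulation it recovers the Poiseuille wall shear
to a fraction of a percent.  In valleys much deeper than the probe
reach the estimator reads the shear layer crossing the valley mouth
and over-estimates the floor shear; the regional shielding comparison
is therefore most meaningful at ridge heights up to the biologically
relevant 0.08.  TAWSS is the magnitude of the cycle-averaged WSS vector
(periodic trapezoidal weights over one cycle) and the oscillatory shear
index is `OSI = 0.5 (1 - |mean vector| / mean |vector|)`, 0 for
unidirectional and 0.5 for perfectly reversing shear.

## Resolution tiers and what the desk-scale tier can and cannot show

Two tiers are used: a desk-scale tier (128 x 64, `t_max = 40`, the tier
used by the test suite and the acceptance script; steady runs take tens
of seconds to a few minutes) and a production tier (512 x 256) for
exploratory use.  The desk-scale tier resolves the channel width by 16
cells and reproduces the smooth-chamber results well: no flow
separation through Re = 10, onset of a closed intracardial vortex with
wall flow reversal between Re = 15 and 20, and a vortex that grows to
fill the chamber by Re ~ 100.

The trabecular valleys are a different matter.  At the biologically
relevant height the ridges are only `hT = 0.064 = 1.3` cells tall --
smaller than the 4-cell support of the regularized delta kernel -- so
the hydrodynamic wall is nearly smooth at this tier and closed
intertrabecular eddies cannot be resolved (the valley flow skims
through with strongly reduced velocity, which the transects and
regional WSS statistics do capture).  Detecting closed valley eddies
requires ridges taller than the kernel footprint, i.e. grids of
256 x 128 or finer for `hT/bV = 0.08`.  A further caveat applies
regardless of resolution: for Re << 1 the steady problem is effectively
Stokes flow and the flow topology is Re-independent, so any sharply
Re-dependent onset of steady valley recirculation in this regime is at
least partly a property of the discretization used to observe it.

## Reproducing the study numbers

`scripts/acceptance.R` reruns the complete desk-scale analysis (steady
and pulsatile bifurcation scans, the bisection for the separation
onset, and the rigid-wall contract) and writes the resulting numbers as
JSON; see the README.  The sweep driver caches per-cell results keyed
by a configuration hash, so interrupted scans resume without rerunning
solvers.

## Known limitations

* 2D, stationary (tethered) walls: no wall motion, no 3D flow
  structures; pulsatile flow through a fixed geometry rather than a
  beating chamber.
* Newtonian fluid; no cells, no hematocrit-dependent rheology.
* The inflow actuator (penalty band) is an idealization of the AV
  canal; quantities are only meaningful downstream of it.
* Valley-scale features at biologically relevant ridge heights need
  finer grids than the desk-scale tier (previous section).
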