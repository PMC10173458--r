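---
title: "Inferring membrane shear viscosity from equilibrium diffusion data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring membrane shear viscosity from equilibrium diffusion data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memvisc)
```

## The problem

The shear viscosity of a lipid membrane, $\mu_m$, sets how fast embedded
proteins and lipids translate and rotate, and therefore the rates of
diffusion-limited processes at membranes.  Measuring $\mu_m$ directly is
hard; equilibrium simulation trajectories, however, give access to lateral
and rotational diffusion coefficients of embedded probes, and hydrodynamic
theory links those to $\mu_m$.  Two complications make the link
non-trivial:

1. the Saffman–Delbrück (SD) theory relates diffusion to viscosity only in
   an *infinite* membrane, while simulations use a small periodic box, and
2. the finite-size effects themselves depend on the unknown viscosity.

`memvisc` implements the full chain — MSD estimation, finite-size
corrections, viscosity inference by four routes, temperature and
composition analysis — together with a Brownian-dynamics generator whose
ground truth follows the same hydrodynamic models, so every stage can be
validated end to end.

## Hydrodynamic models

For a cylindrical inclusion of in-plane radius $R$ spanning a membrane of
thickness $h$ and viscosity $\mu_m$, bounded by solvent of viscosity
$\mu_f$, the SD model gives

$$D^{\mathrm{lat}}_\infty = \frac{k_B T}{4\pi \mu_m h}
  \left[\ln\!\frac{L_{SD}}{R} - \gamma\right], \qquad
  D^{\mathrm{rot}}_\infty = \frac{k_B T}{4\pi \mu_m h R^2},$$

with the SD length $L_{SD} = h\mu_m / (2\mu_f)$ and $\gamma \approx 0.577$
the Euler–Mascheroni constant.  Both expressions hold only for probes much
smaller than $L_{SD}$; the package attaches a structured warning (never a
silent clamp) whenever $R/L_{SD} \ge 0.1$, because analyses near the
validity edge are common and should be visible in the output
(`applicability_warnings()`).

### Finite-size (periodic-boundary) corrections

Rotational motion couples to the periodic images only through the area
fraction of the probe:
$$D^{\mathrm{rot}}_{PBC} = D^{\mathrm{rot}}_\infty
  \left(1 - \frac{A_{\mathrm{prot}}}{A_{\mathrm{box}}}\right),$$
the leading-order angular-momentum compensation in the periodic cell.  It
is the identity as $A_{\mathrm{prot}}/A_{\mathrm{box}} \to 0$, which is why
rotational finite-size effects are small in practice.

Lateral motion couples to the long-ranged membrane flow field and needs
care.  We model the membrane as a 2D viscous sheet of surface viscosity
$\eta = \mu_m h$ sandwiched between solvent slabs of half-thickness $H$
(total solvent per periodic image $2H$).  The in-plane mobility kernel of
this quasi-2D system is $\Lambda(k) = [\eta k^2 + 2\mu_f k \coth(kH)]^{-1}$.
In a flat box ($L \gg L_z = h + 2H$, enforced as $L \ge 3L_z$ with a
warning otherwise) all reciprocal-lattice modes that contribute to the
finite-size difference satisfy $kH \lesssim 1$, where the kernel reduces to
a screened 2D propagator with effective surface viscosity
$\eta_e = \eta + \tfrac{2}{3}\mu_f H$ and screening wavenumber
$\kappa = \sqrt{2\mu_f/(H\eta_e)}$ (so the screening length is
$\kappa^{-1} \approx \sqrt{L_{SD} H}$).  Poisson
resummation of the mode sum then gives the closed form implemented in
`pbc_lateral_delta()`:

$$D^{\mathrm{lat}}_{PBC} - D^{\mathrm{lat}}_\infty =
  \frac{k_B T}{2\eta_e}\left[\frac{1}{2\pi}
  \sum_{\mathbf{m} \neq 0} K_0(\kappa L |\mathbf{m}|)
  - \frac{1}{(\kappa L)^2}\right],$$

a negative term that grows logarithmically with $L$ for $\kappa L \ll 1$
and decays as $-k_B T H/(4\mu_f L^2)$ for large boxes.  The implementation
was cross-checked against an independent direct mode-sum evaluation
(reciprocal-lattice sum plus quadrature of the continuum integral); the two
agree to better than $10^{-6}$ relative.  Because the correction does not
depend on the diffusion coefficient itself, `to_infinite` and
`to_periodic` are exact inverses.

## MSD estimation

`compute_msd()` averages squared displacements over **all** time origins
and over the probes of a group (probe type, optionally leaflet-wise).
Lateral MSD sums both in-plane axes (nm²; two translational degrees of
freedom, so $\mathrm{MSD} = 4D\Delta$); rotational MSD is the squared
cumulative angle about the membrane normal (rad², one degree of freedom,
$\mathrm{MSD} = 2D\Delta$).  Orientation angles are carried as continuous
paths, never reduced mod $2\pi$, and wrapped coordinates are reconstructed
by minimum-image accumulation (`unwrap_lateral()`), which assumes true
per-frame displacements below $L/2$.

`fit_diffusion()` fits an unweighted least-squares line inside a lag
window.  Conventions:

* **Windows.**  Presets follow common practice for these data: 20–40 ns
  for coarse-grained lateral motion, 10–100 ns for single-probe rotation
  and all-atom lateral motion, 0.1–1 µs for polydisperse rotational data.
  Windows should sit in the normal-diffusion regime.
* **Intercept.**  A free intercept is fitted by default so short-time
  non-diffusive offsets do not bias the slope; forcing the origin is
  available.  With an intercept, window sensitivity is second order.
* **Uncertainty.**  MSD points inside a window are strongly correlated, so
  the naive least-squares slope error is far too small.  The reported
  uncertainty instead uses the sampling variance of time-averaged Brownian
  MSD: a trajectory of duration $T$ observed by $m$ independent probe-axes
  has $\mathrm{sd}[\widehat{\mathrm{MSD}}(\Delta)]/\mathrm{MSD}(\Delta)
  \approx \sqrt{4\Delta/(3Tm)}$, evaluated at the window's upper edge.
* **Leaflets.**  When leaflet-wise estimates are combined
  (`leaflet_error()`), the value is their mean and the error their
  absolute difference (a deliberate convention knob; half the difference
  would be the alternative).
* **Thickness.**  `fit_bilayer_thickness()` fits a two-Gaussian mixture to
  a headgroup-marker density profile and returns the center separation;
  coarse-grained analyses bypass the fit with the conventional 4 nm.

## Viscosity inference routes

`fit_membrane_viscosity()` supports four routes, mirroring the distinct
experimental designs (vary probe size at fixed box, or vary box size at
fixed probe):

| method | data | parameters |
|---|---|---|
| `rot_vs_radius` | $D^{\mathrm{rot}}_\infty(R)$ | $\mu_m$ (closed form) |
| `lat_vs_radius` | $D^{\mathrm{lat}}_\infty(R)$ | $\mu_m$ (self-consistent: $\mu_m$ also sits inside the logarithm via $L_{SD}$) |
| `lat_vs_boxsize` | $D^{\mathrm{lat}}_{PBC}(L)$ | $\mu_m$ and $D_\infty$ (the co-fitted intercept) |
| `rot_vs_boxsize` | $D^{\mathrm{rot}}_{PBC}(L)$ | per-box correction + inversion; mean ± spread |

$\mu_m$ is log-parameterised and bracketed on $[10^{-2}, 10^4]$ mPa·s
because membrane viscosities span orders of magnitude across compositions;
a minimum at the bracket edge raises a fit-failure error rather than
returning a clamped value.  For `lat_vs_boxsize` the second parameter is
profiled out analytically ($\hat D_\infty(\mu_m)$ is a mean), leaving a 1D
search.  Uncertainties come from the Gauss–Newton covariance, or from a
bootstrap over points (`bootstrap_uncertainty()`, seeded and
deterministic) when five or more points are available — the bootstrap is
a stand-in for error procedures that depend on unavailable per-dataset
detail, and is labelled as such.

Two properties are worth knowing:

* On noiseless forward data every route recovers $\mu_m$ to better than
  $10^{-6}$ relative (the exactness suite in the tests).
* `lat_vs_boxsize` is the least conditioned route: the box-size signal is
  only ~5–20 % of $D$ at realistic geometries, so a few percent of noise
  in the diffusion coefficients already produces a heavy right tail in
  $\hat\mu_m$ and occasional fit failures.  At the ~1–2 % precision the
  MSD pipeline delivers at the default sampling depth the route is
  unbiased (median within a few percent), but at 5 % noise it is not
  usable on three boxes — the failure signal fires instead.  This is why
  the end-to-end recovery combines routes (below).

`summarize_routes()` reports the cross-route mean and sample standard
deviation ($n-1$); with a single estimate the spread is reported as 0 and
flagged.

## Temperature and composition analysis

`arrhenius_fit()` regresses $\ln(\text{value})$ on $1/T$ and reports
$E_A = |\text{slope}| \cdot R_{\mathrm{gas}}$ in kJ/mol with the sign
convention recorded from the series kind (diffusion decreases, viscosity
increases with $1/T$), so both motions yield comparable positive
activation energies.  Temperature interpolation
(`interpolate_viscosity()`) is piecewise-linear **in T**, not in
$\ln\mu$ vs $1/T$: over the narrow 10 K bracketing intervals of the
packaged tables the two differ by less than the tabulated precision, and
the linear convention is the one the packaged 298 K reference value is
consistent with.  Extrapolation requires an explicit flag.

Composition trends are rule-based on lipid chain descriptors
(`"C1:U1,C2:U2"`): `elongation_increments()` pairs lipids identical except
for a two-carbon elongation of both chains at fixed unsaturation (the
"per methyl group" step convention — one CH₂ pair per chain — which is the
convention consistent with the packaged table's mean of 3.4 mPa·s);
`unsaturation_increments()` pairs lipids of equal chain lengths differing
only in double bonds and divides by the bond-count difference.  All
discovered pairs are returned alongside the mean ± sample sd, because the
pairing rule, not a hard-coded lipid list, defines the statistic; several
natural pairings of the packaged table give per-bond means between 1.5 and
2.1 mPa·s, so no single printed value is asserted.  The gel-phase DSPC row
ships flagged `excluded` (a manual flag — no automatic phase detection),
and DOPC is excluded from the unsaturation statistic as an outlier.
Report rounding is half-away-from-zero at the printed precision; raw
values are always retained.

## The synthetic generator

`build_scenario()` produces datasets with exactly the statistical
structure the analysis assumes: for each (R, L, T) it sets $\mu_m$ from an
Arrhenius law, computes $D_\infty$ from the SD models, maps to $D_{PBC}$
with the finite-size corrections, and simulates Brownian trajectories at
the finite-box coefficients (Gaussian increments of per-axis variance
$2D\,dt$, wrapped into the box; angles accumulated unwrapped).  Noise
enters only through Brownian sampling — exactly what MSD estimation sees —
with no extra measurement noise by default.  Crowding is emulated at the
viscosity level as a separate Arrhenius parameter set, not by simulating
obstacle collisions.

Defaults (chosen once; all synthetic stand-ins labelled as such):

* dilute $E_A = 17.6$ kJ/mol anchored to $\mu_m(315\,\mathrm{K}) = 7.0$
  mPa·s, the consensus of the packaged coarse-grained route table;
* crowded $E_A = 39.6$ kJ/mol anchored to a 27-fold viscosity ratio over
  dilute at 300 K — with these two activation energies the ratio falls to
  ≈6 at 360 K by construction of the Arrhenius forms;
* solvent viscosity: coarse-grained-water-like Arrhenius law, 0.7 mPa·s at
  300 K, $E_A = 10$ kJ/mol (a synthetic model; only its magnitude and
  trend matter);
* geometry: $h = 4$ nm, $H = 2$ nm, probe radius 1.5 nm, box edges
  24/48/72 nm — a box-size/temperature scan in which every box satisfies
  the flat-box condition $L \ge 3L_z$ and every probe stays inside the SD
  bound (the generator *refuses* out-of-regime scenarios rather than
  producing data the analysis should not be applied to);
* sampling: 16 probes, $2\times10^5$ steps of 0.1 ns (a 20 µs
  trajectory).

All randomness flows from one scenario seed: per-system child seeds for
the lateral and rotational simulators are drawn in a single block up
front and recorded in the ground-truth table, so any subset of systems
can be regenerated bit-identically (`simulate_system()`).

What the generator does **not** emulate: hydrodynamic coupling between
probes, anomalous short-time diffusion, lipid-resolution structure,
box-size fluctuations of a pressure-coupled ensemble, and solvent-mediated
interactions.  Passing the end-to-end tests therefore demonstrates the
correctness and statistical calibration of the estimators under the
model's own assumptions, not force-field realism.

## End-to-end recovery

`recover_scenario_viscosity()` runs, per temperature, the two box-size
routes on MSD-fitted diffusion coefficients and combines them by
inverse-variance weighting.  The weighting matters: at the default
sampling the rotational route has ~1–2 % sampling error while the lateral
route has ~20 % (see above), so precision weighting gives a combined
estimate that tracks truth to ~1 % while both routes and their standard
errors remain in the output.  A lateral fit failure at one temperature is
reported (`mu_lat = NA`) and the rotational route carries that
temperature.  An Arrhenius fit of the recovered $\mu_m(T)$ then recovers
the generator's activation energy, typically within a few percent.

```{r endtoend, eval = FALSE}
spec <- scenario_spec(seed = 42)          # 3 box sizes x 5 temperatures
scen <- build_scenario(spec, tables_only = TRUE)
rec  <- recover_scenario_viscosity(scen)  # ~1 min on one core
rec
```

## Numerical choices

* Internal units are nm/ns/K with viscosities in mPa·s; conversion to SI
  happens only inside the equation kernels, and diffusion is reported in
  cm²/s (lateral) and rad²/s (rotational).  `1 nm²/ns = 10⁻⁵ cm²/s`
  exactly.
* The Bessel lattice sum is truncated when a full square shell contributes
  less than $10^{-17}$ of the running total; shells up to
  $\max(60, 45/\kappa L)$ are available, so small-$\kappa L$ cases stay
  converged.
* The 1D viscosity searches use `optimize()` on $\log_{10}\mu_m$ with
  tolerance $10^{-12}$; bracket-edge minima raise errors.
* MSD lag grids default to 48 log-spaced points per decade, deduplicated
  on the frame grid, to bound memory on long trajectories.
* Degenerate inputs fail loudly: non-uniform time grids, wrapped
  coordinates outside $[0, L)$, discontinuous angles, duplicate
  composition keys, non-positive physical quantities, unimodal density
  profiles.

## Problem sizes used by the test suite

The regular suite exercises the stochastic properties at reduced sizes
(e.g. 2×10⁴-step trajectories, 8 probes, 3 temperatures; 20-seed Brownian
recovery checks; 200–300-replicate noise studies).  The acceptance-style
end-to-end check runs one full-size scenario (15 systems × 16 probes ×
2×10⁵ steps) in about a minute.  These sizes are the package's choice of
a thorough-but-quick default; all estimators scale to longer inputs
unchanged.

## Known limitations

* The lateral finite-size correction assumes a flat box and the
  interleaflet-averaged kernel; squat boxes only get a warning, and
  monotopic (non-spanning) probes are treated like spanning ones.
* The heuristic minimum-image unwrapping can mis-assign crossings if the
  box size changes abruptly between frames (a warning counts suspect
  steps); ensemble-corrected unwrapping schemes are out of scope.
* `lat_vs_boxsize` needs either low-noise diffusion data or many box
  sizes; prefer `rot_vs_boxsize` or the combined recovery when available.
* Non-Arrhenius temperature laws (Vogel–Fulcher) and automatic gel-phase
  detection are out of scope; gel-phase rows are excluded manually.
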