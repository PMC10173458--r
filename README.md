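# memvisc

Membrane shear viscosity from equilibrium diffusion data.

`memvisc` is for people who analyse molecular-simulation (or
simulation-like) trajectories of lipid membranes and want a number for the
membrane's shear viscosity μ<sub>m</sub> — the quantity that controls how
fast proteins and lipids translate and rotate in the bilayer, and the
quantity needed to correct periodic-boundary (finite-size) artefacts in
measured diffusion coefficients before comparing them with experiment.

## What it computes

For a cylindrical inclusion of radius *R* in a membrane of thickness *h*
and viscosity μ<sub>m</sub> bounded by solvent of viscosity μ<sub>f</sub>,
the Saffman–Delbrück model gives

    D_lat = kB·T / (4π·μ_m·h) · [ln(L_SD/R) − γ]      L_SD = h·μ_m/(2·μ_f)
    D_rot = kB·T / (4π·μ_m·h·R²)

valid for R/L_SD < 0.1 (the package warns at the edge).  In a periodic
box the measured coefficients are suppressed: rotation by the probe/box
area ratio, `D_rot_PBC = D_rot_∞·(1 − A_prot/A_box)`, and lateral motion
by a flat-box hydrodynamic term computed from a screened quasi-2D mobility
kernel (a Bessel-function lattice sum; see the methods vignette).  The
package provides:

* **MSD estimation** — time- and ensemble-averaged mean-squared
  displacements from wrapped or unwrapped trajectories
  (`unwrap_lateral()`, `compute_msd()`), line fits with the
  `MSD = 4·D·Δ` (lateral) / `2·D·Δ` (rotational) conventions
  (`fit_diffusion()`), leaflet-wise error estimates, and bilayer
  thickness from two-Gaussian density-profile fits.
* **Viscosity inference** — `fit_membrane_viscosity()` with four routes
  (SD fits across probe radii for either motion; finite-size fits across
  box sizes for either motion), returning a classed fit object with
  `print`/`summary`/`coef`/`predict`/`plot` methods, plus cross-route
  summaries (`summarize_routes()`) and seeded bootstrap uncertainties.
* **Temperature & composition analysis** — Arrhenius activation energies
  (`arrhenius_fit()`), linear-in-T interpolation, cholesterol fold
  changes, and rule-based acyl-chain elongation/unsaturation increments
  on shipped viscosity tables.
* **A synthetic generator** — `build_scenario()` creates Brownian
  trajectory ensembles in periodic boxes whose diffusion coefficients
  follow the models above under an Arrhenius viscosity law, with full
  ground truth, so the whole pipeline is testable without any external
  data.
* **A command line** — `inst/scripts/memvisc` with subcommands
  `simulate`, `msd`, `fitd`, `viscosity`, `arrhenius`, `trends`,
  `report` (all thin wrappers over the functions above).

## Worked example

Activation energy of the shipped DOPC viscosity–temperature table and the
consistency of the shipped route estimates:

```r
library(memvisc)

arrhenius_fit(dopc_temperature_series())
#> Arrhenius fit (viscosity, DOPC, 5 temperatures): EA = 29 kJ/mol, ln A = -7.81
#>   R^2 = 0.9517

summarize_routes(cg_route_table()$mu_m)
#> Route summary over 9 estimate(s): mu_m = 7.02 +/- 2.9 mPa.s
```

The 29 kJ/mol is the slope of ln μ<sub>m</sub> vs 1/T times the gas
constant — the temperature sensitivity of the DOPC bilayer's viscosity.
The route summary says nine independent inference routes on one
coarse-grained DPPC bilayer agree to within ±2.9 mPa·s of a 7 mPa·s mean.

End-to-end on synthetic data with known ground truth (reduced sampling so
it runs in seconds; the full-size scan takes about a minute):

```r
spec <- scenario_spec(temperatures = c(300, 330, 360),
                      n_steps = 2e4, n_probes = 8, seed = 7)
scen <- build_scenario(spec, tables_only = TRUE)
recover_scenario_viscosity(scen)
#> lat_vs_boxsize failed at T = 300 K: ... fit hit the viscosity bracket ...
#> lat_vs_boxsize failed at T = 360 K: ... fit hit the viscosity bracket ...
#> Scenario viscosity recovery
#>    T mu_lat mu_rot se_lat  se_rot    mu mu_true rel_err
#>  300     NA  9.192     NA 0.60033 9.192   9.795 0.06163
#>  330  11.59  5.409  9.465 0.29704 5.415   5.158 0.05000
#>  360     NA  2.749     NA 0.06756 2.749   3.022 0.09042
#>   EA recovered 17.9 kJ/mol vs truth 17.6 (rel err 2.0%)
```

Each row is one temperature of a 3-box-size scan: the lateral and
rotational box-size routes (with standard errors), their inverse-variance
weighted combination `mu`, the generator's true viscosity, and the
relative error.  At this reduced sampling the ill-conditioned lateral
route fails at two temperatures (reported, not hidden) while the combined
estimate stays within 10% of truth; at the default sampling depth it is
within ~1%.

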