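## Ground-truth-known synthetic data with the statistical structure the
## analysis assumes: Brownian lateral/rotational probe motion in periodic
## boxes whose diffusion coefficients follow the SD models plus finite-size
## corrections, under an Arrhenius temperature law for the membrane
## viscosity.  All randomness flows from a single scenario seed through a
## documented splitting scheme (one spawned integer seed per system and
## motion, drawn up front).

#' Arrhenius viscosity generator
#'
#' `mu(T) = A * exp(EA / (Rgas * T))` with condition-specific parameters.
#' The packaged defaults contrast a dilute membrane (EA = 17.6 kJ/mol,
#' prefactor anchored so that mu = 7.0 mPa s at 315 K) with a
#' protein-crowded one (EA = 39.6 kJ/mol, anchored to a ~27-fold viscosity
#' ratio over dilute at 300 K).
#'
#' @param T temperature(s), K.
#' @param condition `"dilute"` or `"crowded"` (selects packaged defaults),
#'   ignored when `EA`/`A` are given.
#' @param EA activation energy (kJ/mol).
#' @param A prefactor (mPa s).
#' @return viscosity in mPa s.
#' @export
#' @examples
#' true_viscosity(315)                       # 7.0 mPa.s (dilute default)
#' true_viscosity(300, "crowded") / true_viscosity(300, "dilute")  # ~27
true_viscosity <- function(T, condition = c("dilute", "crowded"),
                           EA = NULL, A = NULL) {
  .check_positive(T = T)
  if (is.null(EA) || is.null(A)) {
    condition <- match.arg(condition)
    p <- .arrhenius_defaults()[[condition]]
    EA <- EA %||% p$EA
    A <- A %||% p$A
  }
  A * exp(EA * 1000 / (physical_constants$gas_constant * T))
}

.arrhenius_defaults <- function() {
  Rg <- physical_constants$gas_constant
  A_dil <- 7.0 / exp(17.6e3 / (Rg * 315))
  mu_dil_300 <- A_dil * exp(17.6e3 / (Rg * 300))
  A_cro <- 27 * mu_dil_300 / exp(39.6e3 / (Rg * 300))
  list(dilute = list(EA = 17.6, A = A_dil),
       crowded = list(EA = 39.6, A = A_cro))
}

#' Synthetic solvent viscosity model
#'
#' A coarse-grained-water-like Arrhenius law anchored at 0.7 mPa s at
#' 300 K with an activation energy of 10 kJ/mol.  This is a synthetic
#' stand-in with a realistic magnitude and temperature trend.
#'
#' @param T temperature(s), K.
#' @return solvent viscosity in mPa s.
#' @export
solvent_viscosity_model <- function(T) {
  .check_positive(T = T)
  Rg <- physical_constants$gas_constant
  A <- 0.7 / exp(10e3 / (Rg * 300))
  A * exp(10e3 / (Rg * T))
}

#' Simulate Brownian lateral motion in a periodic box
#'
#' Per-axis Gaussian displacement increments of variance `2 * D * dt`,
#' accumulated and wrapped into `[0, L)`.  Deterministic given the seed.
#'
#' @param D lateral diffusion coefficient (nm^2/ns), `>= 0`.
#' @param L box edge (nm).
#' @param n_steps number of steps (frames = `n_steps + 1`).
#' @param dt time step (ns), positive.
#' @param n_probes number of independent probes.
#' @param seed integer seed.
#' @return a wrapped [trajectory_ensemble()].
#' @export
simulate_lateral <- function(D, L, n_steps, dt, n_probes = 1L, seed = 1L) {
  if (!is.numeric(D) || D < 0) stop("D must be >= 0", call. = FALSE)
  .check_positive(L = L, n_steps = n_steps, dt = dt, n_probes = n_probes)
  withr_seed(seed, {
    sdst <- sqrt(2 * D * dt)
    nf <- n_steps + 1L
    gen <- function() {
      inc <- matrix(stats::rnorm(n_steps * n_probes, sd = sdst),
                    nrow = n_steps)
      start <- matrix(stats::runif(n_probes, 0, L), nrow = 1,
                      ncol = n_probes)
      apply(rbind(start, inc), 2, cumsum)
    }
    x <- gen(); y <- gen()
    wrap <- function(m) {
      m <- m - floor(m / L) * L
      m[m >= L] <- 0   # guard against round-up to exactly L
      m
    }
    trajectory_ensemble(times = seq(0, by = dt, length.out = nf),
                        x = wrap(x), y = wrap(y), wrapped = TRUE, L = L,
                        leaflet_labels = rep(c("upper", "lower"),
                                             length.out = n_probes))
  })
}

#' Simulate Brownian rotation about the membrane normal
#'
#' One-dimensional Gaussian angle increments of variance `2 * D_rot * dt`,
#' accumulated and never reduced mod `2*pi`.
#'
#' @param D_rot rotational diffusion coefficient (rad^2/ns), `>= 0`.
#' @inheritParams simulate_lateral
#' @return matrix of continuous angles (frames x probes, rad).
#' @export
simulate_rotational <- function(D_rot, n_steps, dt, n_probes = 1L,
                                seed = 1L) {
  if (!is.numeric(D_rot) || D_rot < 0) stop("D_rot must be >= 0",
                                            call. = FALSE)
  .check_positive(n_steps = n_steps, dt = dt, n_probes = n_probes)
  withr_seed(seed, {
    inc <- matrix(stats::rnorm(n_steps * n_probes,
                               sd = sqrt(2 * D_rot * dt)), nrow = n_steps)
    apply(rbind(matrix(0, 1, n_probes), inc), 2, cumsum)
  })
}

#' Synthetic two-peak density profile
#'
#' Two Gaussians centered at `+/- h/2` on a symmetric grid, with optional
#' seeded additive noise — a fixture for headgroup-marker density profiles.
#'
#' @param h bilayer thickness (nm): peak separation.
#' @param width Gaussian width (nm).
#' @param noise additive noise level as a fraction of the peak height.
#' @param n_grid grid points.
#' @param half_span grid half-extent (nm).
#' @param seed integer seed.
#' @return data frame with columns `z` and `density`.
#' @export
synth_density_profile <- function(h = 4, width = 0.4, noise = 0,
                                  n_grid = 201, half_span = 5, seed = 1L) {
  .check_positive(h = h, width = width, n_grid = n_grid,
                  half_span = half_span)
  z <- seq(-half_span, half_span, length.out = n_grid)
  d <- exp(-(z - h / 2)^2 / (2 * width^2)) +
       exp(-(z + h / 2)^2 / (2 * width^2))
  if (noise > 0) {
    d <- withr_seed(seed, pmax(d + stats::rnorm(length(z), sd = noise), 0))
  }
  data.frame(z = z, density = d)
}

#' Scenario specification for the synthetic generator
#'
#' Defaults emulate a single-probe dilute membrane simulated at three box
#' sizes and five temperatures (a box-size/temperature scan): probe radius
#' 1.5 nm, box edges 24/48/72 nm, temperatures 300-360 K, coarse-grained
#' membrane thickness 4 nm, solvent half-thickness 2 nm (so the flat-box
#' condition holds at every size), 16 probes, 2e5 steps of 0.1 ns (20 us).
#'
#' @param radii probe radii (nm).
#' @param box_edges box edges (nm).
#' @param temperatures temperatures (K).
#' @param condition `"dilute"` or `"crowded"` Arrhenius truth.
#' @param EA,A optional explicit Arrhenius parameters (kJ/mol, mPa s).
#' @param h membrane thickness (nm).
#' @param H solvent half-thickness (nm).
#' @param mu_f_model function of T returning solvent viscosity (mPa s).
#' @param n_probes,n_steps,dt sampling parameters (dt in ns).
#' @param seed mandatory integer scenario seed.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(radii = 1.5, box_edges = c(24, 48, 72),
                          temperatures = c(300, 315, 330, 345, 360),
                          condition = "dilute", EA = NULL, A = NULL,
                          h = 4, H = 2,
                          mu_f_model = solvent_viscosity_model,
                          n_probes = 16L, n_steps = 2e5, dt = 0.1,
                          seed) {
  if (missing(seed)) stop("a scenario seed is mandatory", call. = FALSE)
  if (length(radii) == 0 || length(box_edges) == 0 ||
      length(temperatures) == 0) {
    stop("radii, box_edges and temperatures must be non-empty",
         call. = FALSE)
  }
  .check_positive(radii = radii, box_edges = box_edges,
                  temperatures = temperatures, h = h, H = H,
                  n_probes = n_probes, n_steps = n_steps, dt = dt)
  structure(list(radii = radii, box_edges = box_edges,
                 temperatures = temperatures, condition = condition,
                 EA = EA, A = A, h = h, H = H, mu_f_model = mu_f_model,
                 n_probes = as.integer(n_probes),
                 n_steps = as.integer(n_steps), dt = dt,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Build a synthetic scenario with ground truth
#'
#' For every combination of probe radius, box edge and temperature the
#' generator sets the membrane viscosity from the Arrhenius truth, computes
#' the infinite-system diffusion coefficients from the SD models, maps them
#' to finite-box values with the periodic-boundary corrections, and (unless
#' `tables_only`) simulates Brownian trajectories at the finite-box
#' coefficients.  Generation is refused with diagnostics if any system
#' violates the model applicability conditions (probe at/beyond the SD
#' bound, non-flat box, probe area not below box area).
#'
#' @param spec a [scenario_spec()].
#' @param tables_only skip trajectory simulation and return only the
#'   ground-truth diffusion table (used for exact-inversion studies).
#' @param dir optional directory: trajectories are written in the
#'   interchange format together with `ground_truth.json` and a
#'   `manifest.csv`.
#' @return a list of class `scenario` with `spec`, `truth` (data frame:
#'   system id, R, L, T, mu_m, mu_f, D_lat_inf, D_lat_pbc (cm^2/s),
#'   D_rot_inf, D_rot_pbc (rad^2/s), per-system seeds) and, unless
#'   `tables_only` or `dir` given, `trajectories` (list per system with
#'   `lateral` ([trajectory_ensemble()]) and `theta` (angle matrix)).
#' @export
build_scenario <- function(spec, tables_only = FALSE, dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- expand.grid(R = spec$radii, L = spec$box_edges,
                      T = spec$temperatures, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  mu_m <- true_viscosity(grid$T, spec$condition, EA = spec$EA, A = spec$A)
  mu_f <- spec$mu_f_model(grid$T)

  ## applicability screen (refuse, do not warn: truth must be in-regime)
  problems <- character(0)
  lsd <- spec$h * mu_m / (2 * mu_f)
  bad <- grid$R / lsd >= 0.1
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "R/L_SD >= 0.1 for %d system(s), first at R = %g nm, T = %g K (L_SD = %.3g nm)",
      sum(bad), grid$R[which(bad)[1]], grid$T[which(bad)[1]],
      lsd[which(bad)[1]]))
  }
  bad <- grid$L < 3 * (spec$h + 2 * spec$H)
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "flat-box condition L >= 3 L_z violated for %d system(s), smallest L = %g nm",
      sum(bad), min(grid$L[bad])))
  }
  bad <- pi * grid$R^2 >= grid$L^2
  if (any(bad)) {
    problems <- c(problems,
                  "probe cross-section reaches the box area in some system(s)")
  }
  if (length(problems) > 0) {
    stop("scenario refused:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  d_lat_inf <- mapply(function(m, f, T, R)
    .sd_lat_kernel(m, f, spec$h, T, R), mu_m, mu_f, grid$T, grid$R)
  d_rot_inf <- mapply(function(m, T, R)
    .sd_rot_kernel(m, spec$h, T, R), mu_m, grid$T, grid$R)
  d_lat_pbc <- d_lat_inf + mapply(function(L, m, f, T)
    .pbc_delta_kernel(L, spec$H, spec$h, m, f, T), grid$L, mu_m, mu_f,
    grid$T)
  d_rot_pbc <- d_rot_inf * (1 - pi * grid$R^2 / grid$L^2)
  if (any(d_lat_pbc <= 0)) {
    stop("scenario refused: finite-size correction drives D_lat below zero",
         call. = FALSE)
  }

  ## seed splitting: one lateral + one rotational child seed per system,
  ## drawn in one block from the scenario seed
  seeds <- withr_seed(spec$seed,
                      matrix(sample.int(.Machine$integer.max, 2 * n),
                             ncol = 2))
  truth <- data.frame(
    system = sprintf("sys%03d", seq_len(n)),
    R = grid$R, L = grid$L, T = grid$T,
    mu_m = mu_m, mu_f = mu_f, h = spec$h, H = spec$H,
    D_lat_inf = d_lat_inf, D_lat_pbc = d_lat_pbc,
    D_rot_inf = d_rot_inf, D_rot_pbc = d_rot_pbc,
    seed_lat = seeds[, 1], seed_rot = seeds[, 2])

  out <- structure(list(spec = spec, truth = truth), class = "scenario")
  if (tables_only) return(out)

  sims <- lapply(seq_len(n), function(i) simulate_system(out, i))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      tr <- sims[[i]]$lateral
      tr$theta <- sims[[i]]$theta
      write_trajectory(tr, file.path(dir, paste0(truth$system[i], ".tsv")),
                       metadata = as.list(truth[i, c("R", "L", "T", "mu_f",
                                                     "h", "H")]))
    }
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         digits = NA)
    utils::write.csv(truth[, c("system", "R", "L", "T")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  } else {
    out$trajectories <- sims
  }
  out
}

#' Simulate the trajectories of one scenario system
#'
#' Regenerates (deterministically, from the per-system child seeds recorded
#' in the ground truth) the wrapped lateral trajectory and the continuous
#' rotation angles of system `i`.  Used to stream large scenarios one
#' system at a time.
#'
#' @param scenario a [build_scenario()] result (tables are enough).
#' @param i system index into `scenario$truth`.
#' @return list with `lateral` (wrapped [trajectory_ensemble()]) and
#'   `theta` (angle matrix).
#' @export
simulate_system <- function(scenario, i) {
  stopifnot(inherits(scenario, "scenario"))
  tr <- scenario$truth[i, ]
  spec <- scenario$spec
  lat <- simulate_lateral(D = d_report_to_traj(tr$D_lat_pbc, "lateral"),
                          L = tr$L, n_steps = spec$n_steps, dt = spec$dt,
                          n_probes = spec$n_probes, seed = tr$seed_lat)
  th <- simulate_rotational(D_rot = d_report_to_traj(tr$D_rot_pbc,
                                                     "rotational"),
                            n_steps = spec$n_steps, dt = spec$dt,
                            n_probes = spec$n_probes, seed = tr$seed_rot)
  list(lateral = lat, theta = th)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d systems (%d radii x %d boxes x %d temperatures), seed %d\n",
    nrow(x$truth), length(x$spec$radii), length(x$spec$box_edges),
    length(x$spec$temperatures), x$spec$seed))
  invisible(x)
}
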