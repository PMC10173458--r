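# Synthetic generator: Arrhenius truth, Brownian simulators, scenario
# construction with ground-truth self-consistency, and the reduced
# end-to-end pipeline.

test_that("the Arrhenius generator honours its defining limits and defaults", {
  expect_equal(true_viscosity(c(280, 320, 360), EA = 0, A = 3),
               rep(3, 3))
  expect_equal(true_viscosity(315, "dilute"), 7, tolerance = 1e-12)
  r <- true_viscosity(seq(300, 360, 10), "crowded") /
       true_viscosity(seq(300, 360, 10), "dilute")
  expect_equal(r[1], 27, tolerance = 1e-10)
  expect_true(all(diff(r) < 0))
  # round trip through the Arrhenius fit to 6 digits
  Tt <- c(300, 315, 330, 345, 360)
  fit <- arrhenius_fit(thermal_series(Tt, true_viscosity(Tt, "crowded"),
                                      "viscosity"))
  expect_equal(fit$activation_energy, 39.6, tolerance = 1e-6)
})

test_that("the lateral simulator is deterministic with calibrated increments", {
  a <- simulate_lateral(0.05, L = 20, n_steps = 500, dt = 0.1,
                        n_probes = 3, seed = 6)
  b <- simulate_lateral(0.05, L = 20, n_steps = 500, dt = 0.1,
                        n_probes = 3, seed = 6)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_true(a$wrapped)
  expect_true(all(a$x >= 0 & a$x < 20))
  z <- simulate_lateral(0, L = 20, n_steps = 100, dt = 0.1, seed = 1)
  expect_equal(max(abs(diff(z$x))), 0)
  # increment variance: 2 D dt within 4 standard errors
  D <- 0.07; dt <- 0.2
  tr <- unwrap_lateral(simulate_lateral(D, L = 1e4, n_steps = 2e4, dt = dt,
                                        n_probes = 1, seed = 21))
  v <- stats::var(diff(tr$x[, 1]))
  se <- v * sqrt(2 / (2e4 - 1))
  expect_lt(abs(v - 2 * D * dt), 4 * se)
})

test_that("the rotational simulator yields continuous calibrated angles", {
  th0 <- simulate_rotational(0, n_steps = 50, dt = 0.1, n_probes = 2,
                             seed = 3)
  expect_equal(max(abs(th0)), 0)
  th <- simulate_rotational(0.02, n_steps = 2e4, dt = 0.1, n_probes = 4,
                            seed = 13)
  expect_identical(th, simulate_rotational(0.02, n_steps = 2e4, dt = 0.1,
                                           n_probes = 4, seed = 13))
  # MSD fit recovers the input D_rot within 3 standard errors
  tr <- trajectory_ensemble(times = seq(0, by = 0.1, length.out = 2e4 + 1),
                            x = th * 0, y = th * 0, theta = th)
  d <- fit_diffusion(compute_msd(tr, "rotational", lags = seq(1, 20, 1)),
                     fit_window(lower = 1, upper = 20))
  D_hat <- d_report_to_traj(d$value, "rotational")
  se <- d_report_to_traj(d$uncertainty, "rotational")
  expect_lt(abs(D_hat - 0.02), 3 * se)
  # increments are Gaussian: skewness and excess kurtosis within 4 se
  inc <- as.vector(diff(th))
  n <- length(inc)
  zi <- (inc - mean(inc)) / sd(inc)
  expect_lt(abs(mean(zi^3)), 4 * sqrt(6 / n))
  expect_lt(abs(mean(zi^4) - 3), 4 * sqrt(24 / n))
})

test_that("ground truth is self-consistent under the package's own corrections", {
  spec <- scenario_spec(radii = 1.5, box_edges = c(24, 48),
                        temperatures = c(300, 330), seed = 5)
  scen <- build_scenario(spec, tables_only = TRUE)
  tr <- scen$truth
  for (i in seq_len(nrow(tr))) {
    ctx <- sd_context(tr$mu_m[i], tr$mu_f[i], tr$h[i], tr$T[i])
    sys <- membrane_system(tr$L[i], tr$h[i], tr$H[i], tr$T[i])
    lat <- pbc_correct_lateral(diffusion_estimate(tr$D_lat_pbc[i], "lateral"),
                               sys, ctx, "to_infinite")
    expect_lt(abs(lat$value / tr$D_lat_inf[i] - 1), 1e-12)
    rot <- pbc_correct_rotational(
      diffusion_estimate(tr$D_rot_pbc[i], "rotational"), sys,
      probe_spec(tr$R[i]), "to_infinite")
    expect_lt(abs(rot$value / tr$D_rot_inf[i] - 1), 1e-12)
  }
})

test_that("noiseless ground-truth tables invert exactly on every route", {
  spec <- scenario_spec(radii = c(0.8, 1.2, 1.6), box_edges = c(24, 48, 72),
                        temperatures = 315, seed = 8)
  scen <- build_scenario(spec, tables_only = TRUE)
  tr <- scen$truth
  mu_true <- tr$mu_m[1]
  mu_f <- tr$mu_f[1]
  one_L <- tr[tr$L == 48, ]
  f1 <- fit_membrane_viscosity(data.frame(R = one_L$R, D = one_L$D_rot_inf),
                               "rot_vs_radius", h = 4, T = 315, boot = 0)
  f2 <- fit_membrane_viscosity(data.frame(R = one_L$R, D = one_L$D_lat_inf),
                               "lat_vs_radius", h = 4, T = 315,
                               mu_f = mu_f, boot = 0)
  one_R <- tr[tr$R == 1.2, ]
  f3 <- fit_membrane_viscosity(
    data.frame(L = one_R$L, H = one_R$H, D = one_R$D_lat_pbc),
    "lat_vs_boxsize", h = 4, T = 315, mu_f = mu_f, boot = 0)
  f4 <- fit_membrane_viscosity(data.frame(L = one_R$L, D = one_R$D_rot_pbc),
                               "rot_vs_boxsize", h = 4, T = 315,
                               probe = probe_spec(1.2), boot = 0)
  for (f in list(f1, f2, f3, f4)) {
    expect_lt(abs(f$mu_m / mu_true - 1), 1e-6)
  }
})

test_that("scenario generation refuses out-of-regime specifications", {
  expect_error(scenario_spec(radii = numeric(0), seed = 1), "non-empty")
  expect_error(scenario_spec(seed = 1, radii = -1), "positive")
  expect_error(scenario_spec(radii = 1.5, box_edges = 24,
                             temperatures = 300), "seed is mandatory")
  # flat-box violation
  expect_error(build_scenario(scenario_spec(box_edges = 10, seed = 1),
                              tables_only = TRUE), "flat-box")
  # probe beyond the SD bound at high temperature
  expect_error(build_scenario(scenario_spec(radii = 6, seed = 1),
                              tables_only = TRUE), "L_SD")
})

test_that("scenario trajectories are reproducible from their recorded seeds", {
  spec <- scenario_spec(radii = 1.5, box_edges = 24, temperatures = 315,
                        n_steps = 200, n_probes = 2, seed = 17)
  scen <- build_scenario(spec)
  again <- simulate_system(scen, 1)
  expect_identical(scen$trajectories[[1]]$lateral$x, again$lateral$x)
  expect_identical(scen$trajectories[[1]]$theta, again$theta)
})

test_that("scenario directories hold readable trajectories and a manifest", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec(radii = 1.5, box_edges = c(24, 48),
                        temperatures = 315, n_steps = 100, n_probes = 2,
                        seed = 23)
  scen <- build_scenario(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  tr <- read_trajectory(file.path(dir, "sys001.tsv"))
  expect_equal(nrow(tr$x), 101)
  expect_equal(attr(tr, "metadata")$T, 315)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$mu_m, scen$truth$mu_m, tolerance = 1e-12)
})

test_that("density profile fixtures are seeded and recover the thickness", {
  p1 <- synth_density_profile(h = 4, noise = 0.05, seed = 9)
  p2 <- synth_density_profile(h = 4, noise = 0.05, seed = 9)
  expect_identical(p1, p2)
  expect_equal(fit_bilayer_thickness(p1$z, p1$density), 4, tolerance = 0.025)
  clean <- synth_density_profile(h = 3.2, noise = 0)
  expect_equal(fit_bilayer_thickness(clean$z, clean$density), 3.2,
               tolerance = 1e-6)
})

test_that("a reduced box-size/temperature scan recovers viscosity and EA", {
  spec <- scenario_spec(n_steps = 2e4, n_probes = 8,
                        temperatures = c(300, 330, 360), seed = 11)
  scen <- build_scenario(spec, tables_only = TRUE)
  rec <- recover_scenario_viscosity(scen)
  # at 1/20 of the default sampling the combined route still tracks truth
  expect_true(all(rec$per_temperature$rel_err < 0.2))
  expect_lt(rec$EA_rel_err, 0.25)
  expect_s3_class(rec$arrhenius, "arrhenius_fit")
})
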