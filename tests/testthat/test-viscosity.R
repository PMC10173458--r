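# Viscosity inference routes: exact inversion of the forward models,
# cross-route agreement, noise robustness, summaries and bootstrap.

h <- 4; Tk <- 315; mu_f <- 0.7

lat_fwd <- function(mu, R) memvisc:::.sd_lat_kernel(mu, mu_f, h, Tk, R)
rot_fwd <- function(mu, R) memvisc:::.sd_rot_kernel(mu, h, Tk, R)
pbc_fwd <- function(L, H, mu) memvisc:::.pbc_delta_kernel(L, H, h, mu, mu_f, Tk)

test_that("every route inverts its own noiseless forward model to < 1e-6", {
  mu_true <- 7
  R <- c(0.8, 1.2, 1.6, 2)
  L <- c(24, 48, 72)
  pr <- probe_spec(1.5)

  f1 <- fit_membrane_viscosity(
    data.frame(R = R, D = rot_fwd(mu_true, R)), "rot_vs_radius",
    h = h, T = Tk, boot = 0)
  f2 <- fit_membrane_viscosity(
    data.frame(R = R, D = lat_fwd(mu_true, R)), "lat_vs_radius",
    h = h, T = Tk, mu_f = mu_f, boot = 0)
  d_inf <- lat_fwd(mu_true, 1.5)
  f3 <- fit_membrane_viscosity(
    data.frame(L = L, H = 2, D = d_inf + sapply(L, pbc_fwd, H = 2,
                                                mu = mu_true)),
    "lat_vs_boxsize", h = h, T = Tk, mu_f = mu_f, boot = 0)
  f4 <- fit_membrane_viscosity(
    data.frame(L = L, D = rot_fwd(mu_true, 1.5) * (1 - pr$A_prot / L^2)),
    "rot_vs_boxsize", h = h, T = Tk, probe = pr, boot = 0)

  for (f in list(f1, f2, f3, f4)) {
    expect_lt(abs(f$mu_m / mu_true - 1), 1e-6)
  }
  expect_lt(abs(f3$d_infinite / d_inf - 1), 1e-6)
  # one ground truth through four data layouts: tiny cross-route spread
  s <- summarize_routes(list(f1, f2, f3, f4))
  expect_lt(s$spread / s$mean, 0.05)
})

test_that("route fits recover reference viscosities to 4 significant digits", {
  # lateral-vs-radius at 6.9 mPa.s (radii inside the SD validity bound)
  R <- c(0.8, 1.2, 1.6)
  f <- fit_membrane_viscosity(
    data.frame(R = R, D = lat_fwd(6.9, R)), "lat_vs_radius",
    h = h, T = Tk, mu_f = mu_f, boot = 0)
  expect_equal(f$mu_m, 6.9, tolerance = 5e-5)
  # two exact points suffice for the single-parameter model
  f2 <- fit_membrane_viscosity(
    data.frame(R = R[1:2], D = lat_fwd(6.9, R[1:2])), "lat_vs_radius",
    h = h, T = Tk, mu_f = mu_f, boot = 0)
  expect_equal(f2$mu_m, 6.9, tolerance = 5e-5)

  # lateral-vs-boxsize at 7.5 mPa.s, both parameters exact
  L <- c(24, 48, 72)
  d_inf <- lat_fwd(7.5, 1.5)
  f3 <- fit_membrane_viscosity(
    data.frame(L = L, H = 2, D = d_inf + sapply(L, pbc_fwd, H = 2, mu = 7.5)),
    "lat_vs_boxsize", h = h, T = Tk, mu_f = mu_f, boot = 0)
  expect_equal(f3$mu_m, 7.5, tolerance = 5e-5)
  expect_equal(f3$d_infinite, d_inf, tolerance = 5e-5)

  # rotational-vs-boxsize at 13.3 mPa.s: per-box values identical
  pr <- probe_spec(1.5)
  f4 <- fit_membrane_viscosity(
    data.frame(L = L, D = rot_fwd(13.3, 1.5) * (1 - pr$A_prot / L^2)),
    "rot_vs_boxsize", h = h, T = Tk, probe = pr, boot = 0)
  expect_equal(f4$mu_m, 13.3, tolerance = 5e-5)
  expect_equal(f4$uncertainty, 0, tolerance = 1e-8)
})

test_that("boxsize rotational route reduces to the radius route for huge boxes", {
  pr <- probe_spec(1.5)
  L <- c(3000, 5000, 8000)                 # A_prot/A_box < 1e-4
  D <- rot_fwd(9, 1.5) * (1 - pr$A_prot / L^2)
  f_box <- fit_membrane_viscosity(data.frame(L = L, D = D),
                                  "rot_vs_boxsize", h = h, T = Tk,
                                  probe = pr, boot = 0)
  f_rad <- fit_membrane_viscosity(
    data.frame(R = c(1.5, 1.5001), D = rot_fwd(9, c(1.5, 1.5001))),
    "rot_vs_radius", h = h, T = Tk, boot = 0)
  expect_lt(abs(f_box$mu_m / f_rad$mu_m - 1), 0.001)
})

test_that("scaling all lateral D upward lowers the fitted viscosity monotonically", {
  R <- c(0.8, 1.2, 1.8)
  D0 <- lat_fwd(10, R)
  mus <- sapply(c(1, 1.3, 1.8, 2.5), function(k) {
    # large k drives the fitted viscosity toward the SD validity edge;
    # the attached warnings are expected here
    suppressWarnings(
      fit_membrane_viscosity(data.frame(R = R, D = k * D0), "lat_vs_radius",
                             h = h, T = Tk, mu_f = mu_f, boot = 0)$mu_m)
  })
  expect_true(all(diff(mus) < 0))
})

test_that("rot_vs_radius withstands multiplicative noise (median within 5%)", {
  mu_true <- 5
  R <- c(1, 2, 3, 4)
  D0 <- rot_fwd(mu_true, R)
  set.seed(2024)
  est <- replicate(200, {
    D <- D0 * (1 + rnorm(length(R), sd = 0.05))
    fit_membrane_viscosity(data.frame(R = R, D = D), "rot_vs_radius",
                           h = h, T = Tk, boot = 0)$mu_m
  })
  expect_lt(abs(median(est) / mu_true - 1), 0.05)
})

test_that("lat_vs_boxsize is unbiased at its operating noise and invariant to row order", {
  mu_true <- 7.5
  L <- c(24, 48, 72)
  d_inf <- lat_fwd(mu_true, 1.5)
  D0 <- d_inf + sapply(L, pbc_fwd, H = 2, mu = mu_true)
  # 2% multiplicative noise: the precision the MSD pipeline delivers at the
  # default sampling depth.  (At 5% the box-size signal at this geometry is
  # swamped and the route's fit-failure signal fires instead.)
  set.seed(11)
  est <- replicate(200, {
    D <- D0 * (1 + rnorm(3, sd = 0.02))
    tryCatch(fit_membrane_viscosity(
      data.frame(L = L, H = 2, D = D), "lat_vs_boxsize", h = h, T = Tk,
      mu_f = mu_f, boot = 0)$mu_m, error = function(e) NA_real_)
  })
  expect_lt(abs(median(est, na.rm = TRUE) / mu_true - 1), 0.05)
  expect_lt(mean(is.na(est)), 0.1)
  perm <- c(3, 1, 2)
  f_a <- fit_membrane_viscosity(data.frame(L = L, H = 2, D = D0),
                                "lat_vs_boxsize", h = h, T = Tk,
                                mu_f = mu_f, boot = 0)
  f_b <- fit_membrane_viscosity(data.frame(L = L[perm], H = 2, D = D0[perm]),
                                "lat_vs_boxsize", h = h, T = Tk,
                                mu_f = mu_f, boot = 0)
  expect_equal(f_a$mu_m, f_b$mu_m, tolerance = 1e-9)
})

test_that("route summaries use the sample (n-1) spread", {
  s <- summarize_routes(c(6.6, 4.4, 5.5, 4.7, 6.9, 4.6, 9.7, 7.5, 13.3))
  expect_equal(round(s$mean, 1), 7.0)
  expect_equal(round(s$spread, 1), 2.9)
  s2 <- summarize_routes(c(2, 2, 2))
  expect_equal(c(s2$mean, s2$spread), c(2, 0))
  s3 <- summarize_routes(c(1, 2, 3))
  expect_equal(c(s3$mean, s3$spread), c(2, 1))
  s1 <- summarize_routes(5)
  expect_true(s1$single)
  expect_equal(s1$spread, 0)
  expect_error(summarize_routes(numeric(0)), "no estimates")
})

test_that("insufficient data raises the documented signals", {
  expect_error(fit_membrane_viscosity(
    data.frame(R = c(1, 1), D = c(1e6, 1e6)), "rot_vs_radius",
    h = h, T = Tk, boot = 0), "distinct")
  expect_error(fit_membrane_viscosity(
    data.frame(L = c(30, 30), H = 2, D = c(1e-7, 1e-7)), "lat_vs_boxsize",
    h = h, T = Tk, mu_f = mu_f, boot = 0), "distinct")
})

test_that("radius-route results at the validity edge carry warnings", {
  mu_true <- 3                       # L_SD = 8.6 nm: R = 1 nm is past 10%
  R <- c(0.5, 1)
  D <- rot_fwd(mu_true, R)
  expect_warning(f <- fit_membrane_viscosity(
    data.frame(R = R, D = D), "rot_vs_radius", h = h, T = Tk,
    mu_f = mu_f, boot = 0), class = "memvisc_applicability")
  expect_gt(length(applicability_warnings(f)), 0)
})

test_that("bootstrap uncertainty is deterministic and vanishes on noiseless data", {
  R <- c(1, 1.5, 2, 2.5, 3)
  D <- rot_fwd(6, R)
  b1 <- bootstrap_uncertainty(data.frame(R = R, D = D), "rot_vs_radius",
                              h = h, T = Tk, n_resamples = 100, seed = 42)
  b2 <- bootstrap_uncertainty(data.frame(R = R, D = D), "rot_vs_radius",
                              h = h, T = Tk, n_resamples = 100, seed = 42)
  expect_identical(b1, b2)
  expect_lt(as.numeric(b1), 1e-6 * 6)
  # with noise, the bootstrap sd (averaged over datasets: a single draw's
  # bootstrap is itself noisy at n = 5 points) tracks the true sampling sd
  # within a factor 2
  set.seed(9)
  true_sd <- stats::sd(replicate(500, {
    Dn <- D * (1 + rnorm(5, sd = 0.05))
    fit_membrane_viscosity(data.frame(R = R, D = Dn), "rot_vs_radius",
                           h = h, T = Tk, boot = 0)$mu_m
  }))
  set.seed(10)
  bss <- replicate(10, {
    Dn <- D * (1 + rnorm(5, sd = 0.05))
    as.numeric(bootstrap_uncertainty(
      data.frame(R = R, D = Dn), "rot_vs_radius", h = h, T = Tk,
      n_resamples = 200, seed = 7))
  })
  expect_gt(mean(bss), true_sd / 2)
  expect_lt(mean(bss), true_sd * 2)
})

test_that("fit objects expose the standard modelling methods", {
  R <- c(0.8, 1.2, 1.6, 2)
  f <- fit_membrane_viscosity(data.frame(R = R, D = rot_fwd(7, R)),
                              "rot_vs_radius", h = h, T = Tk, boot = 0)
  expect_named(coef(f), "mu_m")
  expect_equal(predict(f), f$points$D, tolerance = 1e-6)
  expect_equal(unname(residuals(f)), rep(0, 4), tolerance = 1e-8)
  expect_output(print(f), "rot_vs_radius")
  expect_output(summary(f), "residual RMS")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
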