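# Independent oracles and frozen golden values.
#
# The goldens were computed before the implementation with an independent
# SI-unit evaluation (numpy/scipy): direct substitution for the SD formulas,
# a closed-form two-point Arrhenius slope, and a direct reciprocal-space
# mode sum (quadrature integral subtraction, no Bessel resummation) for the
# lateral finite-size term.

goldens <- list(
  # T = 315 K, mu_m = 5 mPa.s, mu_f = 0.5 mPa.s, h = 4 nm, R = 2 nm
  sd_lat_cm2s = 2.9856306141147223e-07,
  sd_rot_rad2s = 4326074.412677368,
  # viscosity pair (300 K, 10), (330 K, 5): EA = Rgas ln2 / (1/300 - 1/330)
  arrhenius_two_point_kJmol = 19.018382861425117,
  # lateral finite-size term, h = 4 nm, mu_m = 7, mu_f = 0.7, T = 315 K
  pbc_delta_L24_H2 = -4.519394094627163e-08,
  pbc_delta_L48_H2 = -1.3354484403805016e-08
)

# O(N^2) brute-force time/ensemble-averaged MSD (the estimator oracle)
msd_brute <- function(x, y = NULL, lag_frames) {
  n <- nrow(x)
  vapply(lag_frames, function(d) {
    acc <- 0; cnt <- 0L
    for (t0 in seq_len(n - d)) {
      dx <- x[t0 + d, ] - x[t0, ]
      sq <- dx * dx
      if (!is.null(y)) {
        dy <- y[t0 + d, ] - y[t0, ]
        sq <- sq + dy * dy
      }
      acc <- acc + sum(sq)
      cnt <- cnt + length(sq)
    }
    acc / cnt
  }, numeric(1))
}

# small Brownian trajectory ensembles for estimator tests
make_brownian <- function(D, n_steps, dt, n_probes, seed, L = NULL) {
  set.seed(seed)
  inc <- function() {
    m <- matrix(rnorm(n_steps * n_probes, sd = sqrt(2 * D * dt)),
                nrow = n_steps)
    apply(rbind(matrix(0, 1, n_probes), m), 2, cumsum)
  }
  trajectory_ensemble(times = seq(0, by = dt, length.out = n_steps + 1),
                      x = inc(), y = inc())
}
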