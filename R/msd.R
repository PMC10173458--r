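## Time- and ensemble-averaged mean-squared displacement and the line fits
## that turn MSD slopes into diffusion coefficients:
##   lateral  MSD(lag) = 4 * D * lag   (two in-plane degrees of freedom)
##   rotational MSD(lag) = 2 * D * lag (one angle about the membrane normal)

#' Preset MSD fit windows
#'
#' Lag-time windows (ns) used for diffusion fits: `cg_lateral` 20-40 ns,
#' `cg_rot_polydisperse` 100-1000 ns, `cg_rot_single` 10-100 ns,
#' `aa_lateral` 10-100 ns.
#'
#' @param preset one of the preset names, or `NULL` to pass explicit bounds.
#' @param lower,upper explicit window bounds in ns (used when `preset` is
#'   `NULL`).
#' @return an object of class `fit_window` with fields `lower`, `upper`,
#'   `preset`.
#' @export
#' @examples
#' fit_window("cg_lateral")
#' fit_window(lower = 5, upper = 50)
fit_window <- function(preset = NULL, lower = NULL, upper = NULL) {
  presets <- list(cg_lateral = c(20, 40), cg_rot_polydisperse = c(100, 1000),
                  cg_rot_single = c(10, 100), aa_lateral = c(10, 100))
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    b <- presets[[preset]]
    lower <- b[1]; upper <- b[2]
  } else {
    preset <- NA_character_
  }
  .check_positive(lower = lower, upper = upper)
  if (lower >= upper) stop("fit window must have lower < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper, preset = preset),
            class = "fit_window")
}

#' Default logarithmic lag grid
#'
#' Log-spaced lag times (48 points per decade, deduplicated on the frame
#' grid) between one frame spacing and `max_fraction` of the trajectory
#' length.  Bounds memory for long trajectories.
#'
#' @param traj a [trajectory_ensemble()].
#' @param max_fraction largest lag as a fraction of total duration.
#' @param per_decade grid density.
#' @return numeric vector of lags (ns).
#' @export
default_lags <- function(traj, max_fraction = 0.25, per_decade = 48) {
  dt <- traj$times[2] - traj$times[1]
  n <- length(traj$times)
  max_lag_frames <- max(1, floor((n - 1) * max_fraction))
  frames <- unique(round(10^seq(0, log10(max_lag_frames),
                                by = 1 / per_decade)))
  frames <- frames[frames >= 1 & frames <= n - 1]
  frames * dt
}

#' Time- and ensemble-averaged MSD
#'
#' For every requested lag the squared displacement is averaged over all
#' time origins and over all probes in a group.  Lateral MSD sums the
#' squared displacement over both in-plane axes (nm^2); rotational MSD is
#' the squared cumulative angle change (rad^2).  Probes are grouped by
#' `probe_labels` and, when present and `by_leaflet = TRUE`, by leaflet.
#'
#' @param traj a [trajectory_ensemble()]; must be unwrapped for lateral MSD
#'   and carry continuous angles for rotational MSD.
#' @param kind `"lateral"` or `"rotational"`.
#' @param lags requested lag times (ns); rounded to the frame grid.  Default
#'   [default_lags()].
#' @param by_leaflet group leaflet-wise in addition to probe label.
#' @return a data frame of class `msd_curve` with columns `group`, `lag_ns`,
#'   `msd`, `count` (number of origin-displacement pairs averaged, summed
#'   over probes) and attribute `kind`.
#' @export
compute_msd <- function(traj, kind = c("lateral", "rotational"), lags = NULL,
                        by_leaflet = !is.null(traj$leaflet_labels)) {
  kind <- match.arg(kind)
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (kind == "lateral" && traj$wrapped) {
    stop("lateral MSD requires an unwrapped trajectory; see unwrap_lateral()",
         call. = FALSE)
  }
  if (kind == "rotational" && is.null(traj$theta)) {
    stop("trajectory carries no orientation angles", call. = FALSE)
  }
  dt <- if (length(traj$times) > 1) traj$times[2] - traj$times[1] else
    stop("need at least two frames", call. = FALSE)
  n <- nrow(traj$x)
  if (is.null(lags)) lags <- default_lags(traj)
  lag_frames <- unique(pmin(pmax(round(lags / dt), 1L), n - 1L))
  groups <- traj$probe_labels
  if (by_leaflet && !is.null(traj$leaflet_labels)) {
    groups <- paste(groups, traj$leaflet_labels, sep = "/")
  }
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    msd <- numeric(length(lag_frames))
    cnt <- integer(length(lag_frames))
    for (j in seq_along(lag_frames)) {
      d <- lag_frames[j]
      i1 <- seq_len(n - d)
      if (kind == "lateral") {
        dx <- traj$x[i1 + d, idx, drop = FALSE] - traj$x[i1, idx, drop = FALSE]
        dy <- traj$y[i1 + d, idx, drop = FALSE] - traj$y[i1, idx, drop = FALSE]
        sq <- dx * dx + dy * dy
      } else {
        dth <- traj$theta[i1 + d, idx, drop = FALSE] -
          traj$theta[i1, idx, drop = FALSE]
        sq <- dth * dth
      }
      msd[j] <- mean(sq)
      cnt[j] <- length(sq)
    }
    out[[g]] <- data.frame(group = g, lag_ns = lag_frames * dt,
                           msd = msd, count = cnt)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "kind") <- kind
  attr(res, "meta") <- list(n_frames = n, dt = dt,
                            n_probes = ncol(traj$x) / length(unique(groups)))
  class(res) <- c("msd_curve", class(res))
  res
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary (unweighted) least-squares line through the MSD points whose lag
#' falls inside the window; by default with a free intercept to absorb
#' short-time non-diffusive offsets.  The slope maps to the diffusion
#' coefficient as `slope = 4 D` (lateral) or `slope = 2 D` (rotational), and
#' `D` is reported in cm^2/s or rad^2/s.
#'
#' The reported uncertainty uses the sampling variance of time-averaged
#' Brownian MSD estimates: for a trajectory of duration `T_tot` observed by
#' `m` independent probe-axes, the relative standard deviation of the MSD at
#' lag `lag` is about `sqrt(4*lag / (3*T_tot*m))`, which at the window's
#' upper edge bounds the relative error of the fitted slope.  (The naive
#' least-squares slope error is far too small because MSD points within a
#' window are strongly correlated.)  When the curve carries no trajectory
#' metadata the least-squares error is reported instead.
#'
#' @param msd a single-group [compute_msd()] result (or one group subset).
#' @param window a [fit_window()].
#' @param intercept fit a free intercept (default `TRUE`).
#' @return a [diffusion_estimate()] with `pbc_corrected = FALSE`, the
#'   uncertainty above, and R^2 in `quality`.  A negative fitted slope is
#'   retained but flagged with a warning.
#' @export
fit_diffusion <- function(msd, window, intercept = TRUE) {
  stopifnot(inherits(msd, "msd_curve"), inherits(window, "fit_window"))
  kind <- attr(msd, "kind")
  if (length(unique(msd$group)) > 1) {
    stop("fit_diffusion() expects a single group; subset the MSD curve",
         call. = FALSE)
  }
  sel <- msd$lag_ns >= window$lower & msd$lag_ns <= window$upper
  if (sum(sel) < 3) {
    stop("need at least 3 MSD points inside the fit window", call. = FALSE)
  }
  x <- msd$lag_ns[sel]; y <- msd$msd[sel]
  X <- if (intercept) cbind(1, x) else cbind(x)
  fit <- stats::lm.fit(X, y)
  slope <- fit$coefficients[[if (intercept) 2 else 1]]
  res <- fit$residuals
  dof <- length(y) - length(fit$coefficients)
  sxx <- sum((x - if (intercept) mean(x) else 0)^2)
  se_slope <- if (dof > 0) sqrt(sum(res^2) / dof / sxx) else NA_real_
  r2 <- 1 - sum(res^2) / max(sum((y - mean(y))^2), .Machine$double.xmin)
  fac <- if (kind == "lateral") 4 else 2
  d_traj <- slope / fac                      # nm^2/ns or rad^2/ns
  meta <- attr(msd, "meta")
  unc_traj <- if (!is.null(meta)) {
    t_tot <- (meta$n_frames - 1) * meta$dt
    m_eff <- meta$n_probes * (if (kind == "lateral") 2 else 1)
    abs(d_traj) * sqrt(4 * window$upper / (3 * t_tot * m_eff))
  } else {
    se_slope / fac
  }
  est <- diffusion_estimate(
    value = d_traj_to_report(d_traj, kind), kind = kind,
    pbc_corrected = FALSE,
    uncertainty = d_traj_to_report(unc_traj, kind),
    window = c(window$lower, window$upper), quality = r2)
  if (slope < 0) {
    warning("negative MSD slope: estimate flagged unphysical",
            call. = FALSE)
    attr(est, "unphysical") <- TRUE
  }
  est
}

#' Combine leaflet-wise diffusion estimates
#'
#' The mean of the two leaflet values is reported as the value and their
#' absolute difference as the error estimate.
#'
#' @param a,b [diffusion_estimate()]s of the same kind and correction
#'   status, one per leaflet.
#' @return a combined `diffusion_estimate`.
#' @export
#' @examples
#' a <- diffusion_estimate(10e-8, "lateral")
#' b <- diffusion_estimate(12e-8, "lateral")
#' leaflet_error(a, b)   # value 11e-8, uncertainty 2e-8
leaflet_error <- function(a, b) {
  stopifnot(inherits(a, "diffusion_estimate"),
            inherits(b, "diffusion_estimate"))
  if (a$kind != b$kind || !identical(a$pbc_corrected, b$pbc_corrected)) {
    stop("leaflet estimates must share motion kind and correction status",
         call. = FALSE)
  }
  diffusion_estimate(value = (a$value + b$value) / 2, kind = a$kind,
                     pbc_corrected = a$pbc_corrected,
                     uncertainty = abs(a$value - b$value),
                     window = a$window,
                     quality = mean(c(a$quality, b$quality), na.rm = TRUE))
}

#' Bilayer thickness from a marker density profile
#'
#' Fits a two-Gaussian mixture to a density profile of headgroup marker
#' particles (e.g. phosphorus) along the membrane normal and returns the
#' distance between the two fitted centers.  In coarse-grained mode the
#' fixed conventional thickness of 4 nm is returned regardless of the
#' profile.
#'
#' @param z positions along the membrane normal (nm), strictly increasing.
#' @param density non-negative marker density (arbitrary units).
#' @param cg use the coarse-grained fixed thickness of 4 nm.
#' @return thickness in nm.  Errors with a fit-failure signal on unimodal
#'   profiles.
#' @export
fit_bilayer_thickness <- function(z, density, cg = FALSE) {
  if (isTRUE(cg)) return(4)
  stopifnot(length(z) == length(density), all(diff(z) > 0),
            all(density >= 0))
  ## split at the profile midpoint and locate one peak per half
  mid <- (max(z) + min(z)) / 2
  lo <- z < mid; hi <- !lo
  if (!any(lo) || !any(hi)) stop("degenerate profile grid", call. = FALSE)
  c1 <- z[lo][which.max(density[lo])]
  c2 <- z[hi][which.max(density[hi])]
  if (abs(c2 - c1) < 4 * mean(diff(z))) {
    stop("density profile looks unimodal: cannot fit two Gaussian peaks",
         call. = FALSE)
  }
  df <- data.frame(z = z, d = density)
  s0 <- abs(c2 - c1) / 8
  a0 <- max(density)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ a1 * exp(-(z - m1)^2 / (2 * s1^2)) +
          a2 * exp(-(z - m2)^2 / (2 * s2^2)),
      data = df,
      start = list(a1 = a0, a2 = a0, m1 = c1, m2 = c2, s1 = s0, s2 = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("two-Gaussian fit failed: ",
                             conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  abs(co[["m2"]] - co[["m1"]])
}
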