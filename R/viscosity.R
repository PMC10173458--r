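## Four routes from diffusion data to membrane shear viscosity mu_m:
##   rot_vs_radius  : SD rotational model fitted across probe radii
##   lat_vs_radius  : SD lateral model fitted across probe radii
##                    (mu_m also enters through the SD length; solved
##                    self-consistently)
##   lat_vs_boxsize : lateral finite-size dependence fitted across box edges
##                    (two parameters: mu_m and D_inf)
##   rot_vs_boxsize : rotational finite-size correction per box, then SD
##                    rotational inversion; aggregated over boxes

## ---- warning-free model kernels (viscosities in mPa.s, lengths nm, K) ----

.sd_lat_kernel <- function(mu_m, mu_f, h, T, R) {
  kc <- physical_constants
  lsd <- h * mu_m / (2 * mu_f)
  kc$boltzmann_constant * T / (4 * pi * .mPas(mu_m) * .nm(h)) *
    (log(lsd / R) - kc$euler_mascheroni) * 1e4          # cm^2/s
}

.sd_rot_kernel <- function(mu_m, h, T, R) {
  physical_constants$boltzmann_constant * T /
    (4 * pi * .mPas(mu_m) * .nm(h) * .nm(R)^2)          # rad^2/s
}

.pbc_delta_kernel <- function(L, H, h, mu_m, mu_f, T) {
  kc <- physical_constants
  eta_e <- .mPas(mu_m) * .nm(h) + (2 / 3) * .mPas(mu_f) * .nm(H)
  kappa <- sqrt(2 * .mPas(mu_f) / (.nm(H) * eta_e))
  vapply(L, function(Li) {
    x <- kappa * .nm(Li)
    kc$boltzmann_constant * T / (2 * eta_e) *
      (.k0_lattice_sum(x) / (2 * pi) - 1 / x^2) * 1e4   # cm^2/s
  }, numeric(1))
}

.MU_BRACKET <- c(1e-2, 1e4)   # mPa.s search bracket, log-parameterized

## ---- the fitting front end -------------------------------------------------

#' Fit membrane shear viscosity from diffusion data
#'
#' The main modelling function of the package.  Given diffusion coefficients
#' of membrane-embedded probes it infers the membrane shear viscosity
#' `mu_m` by one of four routes:
#'
#' * `"rot_vs_radius"`: least-squares fit of the SD rotational model to
#'   PBC-corrected `D_inf_rot` across probe radii (closed-form in `mu_m`).
#'   `points` needs columns `R` (nm) and `D` (rad^2/s).
#' * `"lat_vs_radius"`: self-consistent single-parameter fit of the SD
#'   lateral model to PBC-corrected `D_inf_lat` across radii (`mu_m` also
#'   enters through the SD length inside the logarithm).  `points` needs
#'   `R` and `D` (cm^2/s); `mu_f` required.
#' * `"lat_vs_boxsize"`: two-parameter fit (`mu_m`, `D_inf`) of the lateral
#'   finite-size model to uncorrected `D_PBC_lat` across box edges.
#'   `points` needs `L` (nm) and `D` (cm^2/s), plus `H` per point or via
#'   the `H` argument; `mu_f` required.
#' * `"rot_vs_boxsize"`: per-box rotational finite-size correction followed
#'   by SD rotational inversion; the estimate is the mean over boxes and
#'   the uncertainty their sample standard deviation.  `points` needs `L`
#'   and `D` (rad^2/s); `probe` required.
#'
#' `mu_m` is log-parameterized and bracketed on `[1e-2, 1e4]` mPa s.
#' Uncertainties come from the Gauss-Newton covariance, or from a bootstrap
#' over points when `n >= 5` (see [bootstrap_uncertainty()]); `boot = 0`
#' disables the bootstrap.
#'
#' @param points data frame of diffusion points (see above).  Column `D`
#'   always uses reporting units (cm^2/s lateral, rad^2/s rotational).
#' @param method one of the four route names.
#' @param h membrane thickness (nm).
#' @param T temperature (K).
#' @param mu_f solvent viscosity (mPa s); required by the lateral routes.
#' @param probe a [probe_spec()]; required by `rot_vs_boxsize`.
#' @param H solvent half-thickness (nm) for `lat_vs_boxsize` when not a
#'   column of `points`.
#' @param boot number of bootstrap resamples used for the uncertainty when
#'   `nrow(points) >= 5` (default 200); `0` disables.
#' @param seed seed for the bootstrap.
#' @return an object of class `memvisc_fit` with components `mu_m` (mPa s),
#'   `uncertainty`, `method`, `d_infinite` (co-fitted `D_inf`, box-size
#'   lateral route only), `eta` (surface viscosity, mPa s nm), `L_SD` (nm),
#'   `context` ([sd_context()] at the fitted viscosity), `points`,
#'   `fitted`, `residuals`.  Applicability warnings of the inputs (probe
#'   radius vs SD length, non-flat boxes) are unioned onto the result.
#' @seealso [summarize_routes()], [bootstrap_uncertainty()]
#' @export
#' @examples
#' ctx <- sd_context(mu_m = 5, mu_f = 0.5, h = 4, T = 315)
#' pts <- data.frame(R = 1:4)
#' pts$D <- sapply(pts$R, function(r)
#'   suppressWarnings(sd_rotational_diffusion(ctx, probe_spec(r))))
#' fit_membrane_viscosity(pts, "rot_vs_radius", h = 4, T = 315)
fit_membrane_viscosity <- function(points,
                                   method = c("rot_vs_radius",
                                              "lat_vs_radius",
                                              "lat_vs_boxsize",
                                              "rot_vs_boxsize"),
                                   h, T, mu_f = NULL, probe = NULL, H = NULL,
                                   boot = 200, seed = 1L) {
  method <- match.arg(method)
  .check_positive(h = h, T = T)
  points <- as.data.frame(points)
  if (!"D" %in% names(points)) stop("`points` needs a column `D`",
                                    call. = FALSE)
  n <- nrow(points)
  res <- switch(method,
    rot_vs_radius = .fit_rot_vs_radius(points, h, T),
    lat_vs_radius = .fit_lat_vs_radius(points, h, T, mu_f),
    lat_vs_boxsize = .fit_lat_vs_boxsize(points, h, T, mu_f, H),
    rot_vs_boxsize = .fit_rot_vs_boxsize(points, h, T, probe))
  mu <- res$mu_m
  unc <- res$uncertainty
  if (boot > 0 && n >= 5) {
    bs <- bootstrap_uncertainty(points, method, h = h, T = T, mu_f = mu_f,
                                probe = probe, H = H, n_resamples = boot,
                                seed = seed)
    if (!isTRUE(attr(bs, "unreliable"))) unc <- as.numeric(bs)
  }
  out <- structure(list(
    mu_m = mu, uncertainty = unc, method = method,
    d_infinite = res$d_infinite,
    eta = mu * h,
    L_SD = if (!is.null(mu_f)) h * mu / (2 * mu_f) else NA_real_,
    context = if (!is.null(mu_f)) sd_context(mu, mu_f, h, T) else NULL,
    h = h, T = T, mu_f = mu_f, probe = probe, H = H,
    points = points, fitted = res$fitted,
    residuals = points$D - res$fitted,
    n = n), class = "memvisc_fit")
  ## union applicability warnings from the fitted geometry
  msgs <- character(0)
  if (!is.null(mu_f) && "R" %in% names(points)) {
    lsd <- h * mu / (2 * mu_f)
    bad <- points$R / lsd >= 0.1
    if (any(bad)) {
      msgs <- c(msgs, sprintf(
        "%d of %d probe radii at or beyond the SD validity bound (R/L_SD >= 0.1)",
        sum(bad), n))
    }
  }
  if ("L" %in% names(points) && !is.null(out$H %||% points$H)) {
    Hs <- points$H %||% rep(H, n)
    bad <- points$L < 3 * (h + 2 * Hs)
    if (any(bad)) {
      msgs <- c(msgs, sprintf("%d of %d boxes are not flat (L < 3 L_z)",
                              sum(bad), n))
    }
  }
  .applicability_warn(out, msgs)
}

.fit_rot_vs_radius <- function(points, h, T) {
  if (!"R" %in% names(points)) stop("`points` needs a column `R` (nm)",
                                    call. = FALSE)
  if (length(unique(points$R)) < 2) {
    stop("rot_vs_radius needs >= 2 distinct probe radii", call. = FALSE)
  }
  ## D_i = a_i / mu with a_i = kB T/(4 pi h R_i^2) (unit-adjusted):
  ## least squares has the closed form mu = sum(a^2) / sum(D a)
  a <- .sd_rot_kernel(1, h, T, points$R)
  mu <- sum(a^2) / sum(points$D * a)
  if (mu <= 0) stop("rotational data imply a non-positive viscosity",
                    call. = FALSE)
  fitted <- a / mu
  list(mu_m = mu, d_infinite = NULL, fitted = fitted,
       uncertainty = .gn_uncertainty(points$D, fitted, function(m)
         .sd_rot_kernel(m, h, T, points$R), mu))
}

.fit_lat_vs_radius <- function(points, h, T, mu_f) {
  if (is.null(mu_f)) stop("lat_vs_radius requires `mu_f`", call. = FALSE)
  if (!"R" %in% names(points)) stop("`points` needs a column `R` (nm)",
                                    call. = FALSE)
  obj <- function(lmu) {
    pred <- .sd_lat_kernel(10^lmu, mu_f, h, T, points$R)
    sum((points$D - pred)^2)
  }
  opt <- stats::optimize(obj, log10(.MU_BRACKET), tol = 1e-12)
  mu <- 10^opt$minimum
  if (min(abs(log10(mu / .MU_BRACKET))) < 1e-3) {
    stop(sprintf(paste0("lat_vs_radius fit hit the viscosity bracket ",
                        "[%g, %g] mPa.s; residual sum %g"),
                 .MU_BRACKET[1], .MU_BRACKET[2], opt$objective),
         call. = FALSE)
  }
  fitted <- .sd_lat_kernel(mu, mu_f, h, T, points$R)
  list(mu_m = mu, d_infinite = NULL, fitted = fitted,
       uncertainty = .gn_uncertainty(points$D, fitted, function(m)
         .sd_lat_kernel(m, mu_f, h, T, points$R), mu))
}

.fit_lat_vs_boxsize <- function(points, h, T, mu_f, H) {
  if (is.null(mu_f)) stop("lat_vs_boxsize requires `mu_f`", call. = FALSE)
  if (!"L" %in% names(points)) stop("`points` needs a column `L` (nm)",
                                    call. = FALSE)
  Hs <- points$H %||% if (!is.null(H)) rep(H, nrow(points)) else
    stop("lat_vs_boxsize requires `H` (argument or column)", call. = FALSE)
  if (length(unique(points$L)) < 2) {
    stop("lat_vs_boxsize needs >= 2 distinct box edges", call. = FALSE)
  }
  ## profile out D_inf: for fixed mu, LS gives D_inf = mean(D - delta(mu))
  delta_at <- function(mu) {
    mapply(function(Li, Hi) .pbc_delta_kernel(Li, Hi, h, mu, mu_f, T),
           points$L, Hs)
  }
  obj <- function(lmu) {
    dd <- delta_at(10^lmu)
    r <- points$D - dd
    sum((r - mean(r))^2)
  }
  opt <- stats::optimize(obj, log10(.MU_BRACKET), tol = 1e-12)
  mu <- 10^opt$minimum
  if (min(abs(log10(mu / .MU_BRACKET))) < 1e-3) {
    stop(sprintf(paste0("lat_vs_boxsize fit hit the viscosity bracket ",
                        "[%g, %g] mPa.s; residual sum %g"),
                 .MU_BRACKET[1], .MU_BRACKET[2], opt$objective),
         call. = FALSE)
  }
  dd <- delta_at(mu)
  d_inf <- mean(points$D - dd)
  fitted <- d_inf + dd
  unc <- .gn_uncertainty(points$D, fitted, function(m) {
    ddm <- mapply(function(Li, Hi) .pbc_delta_kernel(Li, Hi, h, m, mu_f, T),
                  points$L, Hs)
    mean(points$D - ddm) + ddm
  }, mu)
  list(mu_m = mu, d_infinite = d_inf, fitted = fitted, uncertainty = unc)
}

.fit_rot_vs_boxsize <- function(points, h, T, probe) {
  if (is.null(probe)) stop("rot_vs_boxsize requires `probe`", call. = FALSE)
  stopifnot(inherits(probe, "probe_spec"))
  if (!"L" %in% names(points)) stop("`points` needs a column `L` (nm)",
                                    call. = FALSE)
  if (nrow(points) < 2) {
    stop("rot_vs_boxsize needs >= 2 boxes", call. = FALSE)
  }
  frac <- probe$A_prot / points$L^2
  if (any(frac >= 1)) stop("A_prot must be smaller than every box area",
                           call. = FALSE)
  d_inf <- points$D / (1 - frac)
  mu_i <- .sd_rot_kernel(1, h, T, probe$R) / d_inf
  mu <- mean(mu_i)
  list(mu_m = mu, d_infinite = NULL,
       fitted = .sd_rot_kernel(mu, h, T, probe$R) * (1 - frac),
       uncertainty = stats::sd(mu_i))
}

## Gauss-Newton 1-parameter uncertainty: sigma_mu^2 = s^2 / sum(J^2),
## J = d pred / d mu (central difference).  Exactly 0 on noiseless data.
.gn_uncertainty <- function(D, fitted, pred_fn, mu) {
  dof <- length(D) - 1L
  if (dof < 1) return(NA_real_)
  s2 <- sum((D - fitted)^2) / dof
  dm <- mu * 1e-5
  J <- (pred_fn(mu + dm) - pred_fn(mu - dm)) / (2 * dm)
  ssj <- sum(J^2)
  if (ssj == 0) return(NA_real_)
  sqrt(s2 / ssj)
}

## ---- methods ---------------------------------------------------------------

#' @export
print.memvisc_fit <- function(x, ...) {
  cat(sprintf("Membrane shear viscosity fit (%s, n = %d)\n", x$method, x$n))
  cat(sprintf("  mu_m = %.4g mPa.s%s\n", x$mu_m,
              if (is.finite(x$uncertainty))
                sprintf(" +/- %.2g", x$uncertainty) else ""))
  if (!is.null(x$d_infinite))
    cat(sprintf("  D_inf = %.4g cm^2/s (co-fitted)\n", x$d_infinite))
  if (is.finite(x$L_SD))
    cat(sprintf("  eta = %.4g mPa.s.nm,  L_SD = %.4g nm\n", x$eta, x$L_SD))
  w <- applicability_warnings(x)
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.memvisc_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual RMS: %.3g (units of D)\n",
              sqrt(mean(object$residuals^2))))
  invisible(object)
}

#' @export
coef.memvisc_fit <- function(object, ...) {
  co <- c(mu_m = object$mu_m)
  if (!is.null(object$d_infinite)) co <- c(co, d_inf = object$d_infinite)
  co
}

#' Predicted diffusion coefficients from a viscosity fit
#'
#' @param object a `memvisc_fit`.
#' @param newdata optional data frame with the same predictor columns as the
#'   fit (`R`, or `L`/`H`); defaults to the fitted points.
#' @param ... unused.
#' @return numeric vector of predicted `D` in the route's reporting units.
#' @export
predict.memvisc_fit <- function(object, newdata = NULL, ...) {
  pts <- if (is.null(newdata)) object$points else as.data.frame(newdata)
  switch(object$method,
    rot_vs_radius = .sd_rot_kernel(object$mu_m, object$h, object$T, pts$R),
    lat_vs_radius = .sd_lat_kernel(object$mu_m, object$mu_f, object$h,
                                   object$T, pts$R),
    lat_vs_boxsize = {
      Hs <- pts$H %||% rep(object$H, nrow(pts))
      object$d_infinite + mapply(function(Li, Hi)
        .pbc_delta_kernel(Li, Hi, object$h, object$mu_m, object$mu_f,
                          object$T), pts$L, Hs)
    },
    rot_vs_boxsize = .sd_rot_kernel(object$mu_m, object$h, object$T,
                                    object$probe$R) *
      (1 - object$probe$A_prot / pts$L^2))
}

#' @export
residuals.memvisc_fit <- function(object, ...) object$residuals

#' @export
plot.memvisc_fit <- function(x, ...) {
  pred_x <- if (grepl("radius", x$method)) x$points$R else x$points$L
  xl <- if (grepl("radius", x$method)) "R (nm)" else "L (nm)"
  yl <- if (grepl("rot", x$method)) "D (rad^2/s)" else "D (cm^2/s)"
  graphics::plot(pred_x, x$points$D, xlab = xl, ylab = yl,
                 main = sprintf("%s: mu_m = %.3g mPa.s", x$method, x$mu_m),
                 ...)
  ord <- order(pred_x)
  graphics::lines(pred_x[ord], x$fitted[ord], col = 2)
  invisible(x)
}

## ---- cross-route summary and bootstrap ------------------------------------

#' Summarize viscosity estimates across routes
#'
#' @param estimates a list of `memvisc_fit` objects, or a numeric vector of
#'   viscosities (mPa s).
#' @return an object of class `route_summary` with `values`, `mean` and
#'   `spread` (sample standard deviation, `n - 1` denominator; reported as 0
#'   and flagged when only one estimate is supplied).
#' @export
#' @examples
#' summarize_routes(c(6.6, 4.4, 5.5, 4.7, 6.9, 4.6, 9.7, 7.5, 13.3))
summarize_routes <- function(estimates) {
  vals <- if (is.numeric(estimates)) {
    estimates
  } else {
    vapply(estimates, function(e) {
      stopifnot(inherits(e, "memvisc_fit"))
      e$mu_m
    }, numeric(1))
  }
  if (length(vals) == 0) stop("no estimates supplied", call. = FALSE)
  structure(list(values = vals, mean = mean(vals),
                 spread = if (length(vals) > 1) stats::sd(vals) else 0,
                 single = length(vals) == 1),
            class = "route_summary")
}

#' @export
print.route_summary <- function(x, ...) {
  cat(sprintf("Route summary over %d estimate(s): mu_m = %.3g +/- %.3g mPa.s%s\n",
              length(x$values), x$mean, x$spread,
              if (x$single) " (single estimate; spread not estimable)" else ""))
  invisible(x)
}

#' Bootstrap uncertainty of a viscosity route
#'
#' Standard deviation of the route estimate over resamples-with-replacement
#' of the diffusion points.  Deterministic given `seed`.
#'
#' @inheritParams fit_membrane_viscosity
#' @param n_resamples number of bootstrap resamples.
#' @return the bootstrap standard deviation (mPa s).  If more than 20% of
#'   resamples fail to fit, the result carries attribute `unreliable = TRUE`
#'   and a warning is raised.
#' @export
bootstrap_uncertainty <- function(points, method, h, T, mu_f = NULL,
                                  probe = NULL, H = NULL,
                                  n_resamples = 200, seed = 1L) {
  points <- as.data.frame(points)
  if (nrow(points) < 3) stop("bootstrap needs >= 3 points", call. = FALSE)
  fit1 <- function(p) {
    switch(method,
      rot_vs_radius = .fit_rot_vs_radius(p, h, T)$mu_m,
      lat_vs_radius = .fit_lat_vs_radius(p, h, T, mu_f)$mu_m,
      lat_vs_boxsize = .fit_lat_vs_boxsize(p, h, T, mu_f, H)$mu_m,
      rot_vs_boxsize = .fit_rot_vs_boxsize(p, h, T, probe)$mu_m)
  }
  vals <- withr_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(nrow(points), replace = TRUE)
      tryCatch(fit1(points[idx, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
  })
  fail <- mean(is.na(vals))
  out <- stats::sd(vals, na.rm = TRUE)
  if (fail > 0.2) {
    warning(sprintf("bootstrap unreliable: %.0f%% of resamples failed",
                    100 * fail), call. = FALSE)
    attr(out, "unreliable") <- TRUE
  }
  out
}

## evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
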