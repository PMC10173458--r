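## Finite-size (periodic-boundary) corrections for diffusion measured in a
## flat periodic box.  Lateral motion couples to the periodically replicated
## membrane + solvent-slab flow field; the correction below follows from the
## quasi-2D mobility kernel 1/(eta k^2 + 2 mu_f k coth(kH)) summed over the
## reciprocal lattice (Poisson resummation gives a Bessel-K0 lattice sum).
## Rotational motion couples only through the area fraction of the probe.

#' Diffusion estimate container
#'
#' A fitted (or model-generated) diffusion coefficient with its units,
#' finite-size status and fit metadata.
#'
#' @param value diffusion coefficient; cm^2/s for lateral motion, rad^2/s for
#'   rotational motion.
#' @param kind `"lateral"` or `"rotational"`.
#' @param pbc_corrected logical; `FALSE` for a raw finite-box value
#'   (`D_PBC`), `TRUE` for an infinite-system value (`D_inf`).
#' @param uncertainty optional, same units as `value`.
#' @param window optional fit window, lag interval in ns (length-2 numeric).
#' @param quality optional fit diagnostic (e.g. R^2).
#' @return an object of class `diffusion_estimate`.
#' @export
diffusion_estimate <- function(value, kind = c("lateral", "rotational"),
                               pbc_corrected = FALSE, uncertainty = NA_real_,
                               window = c(NA_real_, NA_real_),
                               quality = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), length(value) == 1L)
  if (is.finite(value) && value <= 0) {
    warning("non-positive diffusion coefficient retained for diagnostics",
            call. = FALSE)
  }
  structure(list(value = value, kind = kind, pbc_corrected = pbc_corrected,
                 uncertainty = uncertainty, window = window,
                 quality = quality,
                 unit = if (kind == "lateral") "cm^2/s" else "rad^2/s"),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("%s diffusion: D_%s = %.4g %s%s\n",
              x$kind, if (x$pbc_corrected) "inf" else "PBC", x$value, x$unit,
              if (is.finite(x$uncertainty))
                sprintf(" +/- %.2g", x$uncertainty) else ""))
  if (all(is.finite(x$window)))
    cat(sprintf("  fit window: %g-%g ns\n", x$window[1], x$window[2]))
  invisible(x)
}

## Bessel-K0 lattice sum over m in Z^2 \ {0}; x = kappa * L.
## Terms decay as exp(-x |m|); shells are added until machine-negligible.
.k0_lattice_sum <- function(x) {
  stopifnot(x > 0)
  total <- 0
  max_s <- max(60L, ceiling(45 / x))   # K0 decays once kappa*L*|m| > ~1
  for (s in seq_len(max_s)) {
    ix <- seq(-s, s)
    ## shell of the square lattice at Chebyshev radius s
    pts <- rbind(cbind(ix, s), cbind(ix, -s),
                 cbind(s, seq(-s + 1, s - 1)), cbind(-s, seq(-s + 1, s - 1)))
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    term <- sum(besselK(x * r, 0))
    total <- total + term
    if (term < 1e-17 * max(total, 1e-300)) break
  }
  total
}

#' Lateral finite-size correction term for a flat periodic box
#'
#' The difference `D_PBC - D_inf` (cm^2/s) for lateral diffusion in a
#' periodic box of edge `L` holding a membrane of thickness `h` and shear
#' viscosity `mu_m` with solvent slabs of half-thickness `H` and viscosity
#' `mu_f`:
#' \deqn{\Delta D = \frac{k_B T}{2\eta_e}\left[\frac{1}{2\pi}
#'   \sum_{m \neq 0} K_0(\kappa L |m|) - \frac{1}{(\kappa L)^2}\right]}
#' with effective surface viscosity `eta_e = mu_m*h + (2/3)*mu_f*H` and
#' screening wavenumber `kappa = sqrt(2*mu_f / (H*eta_e))`
#' (`1/kappa ~ sqrt(L_SD * H)`).  The term is negative (periodic images slow
#' the probe down), grows logarithmically with `L` for `kappa*L << 1` and
#' vanishes as `-kB*T*H/(4*mu_f*L^2)` for large boxes.
#'
#' @param L lateral box edge (nm).
#' @param H solvent half-thickness (nm).
#' @param ctx an [sd_context()] (supplies `mu_m`, `mu_f`, `h`, `T`).
#' @return correction `D_PBC - D_inf` in cm^2/s (negative).
#' @export
pbc_lateral_delta <- function(L, H, ctx) {
  stopifnot(inherits(ctx, "sd_context"))
  .check_positive(L = L, H = H)
  kc <- physical_constants
  eta_e <- .mPas(ctx$mu_m) * .nm(ctx$h) + (2 / 3) * .mPas(ctx$mu_f) * .nm(H)
  kappa <- sqrt(2 * .mPas(ctx$mu_f) / (.nm(H) * eta_e))   # 1/m
  x <- kappa * .nm(L)
  dd_si <- kc$boltzmann_constant * ctx$T / (2 * eta_e) *
    (.k0_lattice_sum(x) / (2 * pi) - 1 / x^2)             # m^2/s
  dd_si * 1e4                                             # cm^2/s
}

#' Apply or remove the lateral finite-size correction
#'
#' Maps a lateral diffusion estimate between the finite periodic system
#' (`D_PBC`) and the infinite system (`D_inf`).  The two directions are exact
#' inverses because the correction term does not depend on the diffusion
#' coefficient itself.
#'
#' @param d a lateral [diffusion_estimate()].
#' @param system a [membrane_system()]; a structured warning is attached if
#'   the box is not flat (`L < 3 * L_z`).
#' @param ctx an [sd_context()] whose `mu_m` is the membrane viscosity used
#'   in the correction.
#' @param direction `"to_infinite"` (requires an uncorrected estimate) or
#'   `"to_periodic"` (requires a corrected one).
#' @return a new `diffusion_estimate` with `pbc_corrected` toggled.
#' @export
pbc_correct_lateral <- function(d, system, ctx,
                                direction = c("to_infinite", "to_periodic")) {
  direction <- match.arg(direction)
  stopifnot(inherits(d, "diffusion_estimate"),
            inherits(system, "membrane_system"))
  if (d$kind != "lateral") {
    stop("pbc_correct_lateral() requires a lateral diffusion estimate",
         call. = FALSE)
  }
  if (direction == "to_infinite" && isTRUE(d$pbc_corrected)) {
    stop("estimate is already PBC-corrected", call. = FALSE)
  }
  if (direction == "to_periodic" && !isTRUE(d$pbc_corrected)) {
    stop("estimate is already a finite-box value", call. = FALSE)
  }
  dd <- pbc_lateral_delta(system$L, system$H, ctx)
  out <- d
  out$value <- if (direction == "to_infinite") d$value - dd else d$value + dd
  out$pbc_corrected <- direction == "to_infinite"
  msgs <- if (!is_flat_box(system)) {
    sprintf(paste0("box is not flat: L = %g nm < 3 * L_z = %g nm; ",
                   "the lateral finite-size correction assumes a flat box"),
            system$L, 3 * system$Lz)
  } else character(0)
  out <- .applicability_warn(out, c(applicability_warnings(d), msgs))
  out
}

#' Apply or remove the rotational finite-size correction
#'
#' Rotational diffusion in a periodic cell is suppressed purely by the area
#' fraction of the probe: `D_PBC_rot = D_inf_rot * (1 - A_prot / A_box)` with
#' `A_box = L^2`.  The correction is the identity as `A_prot/A_box -> 0` and
#' the two directions are exact inverses.
#'
#' @param d a rotational [diffusion_estimate()].
#' @param system a [membrane_system()].
#' @param probe a [probe_spec()]; `A_prot` must be smaller than `A_box`.
#' @param direction `"to_infinite"` or `"to_periodic"`.
#' @return a new `diffusion_estimate` with `pbc_corrected` toggled.
#' @export
pbc_correct_rotational <- function(d, system, probe,
                                   direction = c("to_infinite", "to_periodic")) {
  direction <- match.arg(direction)
  stopifnot(inherits(d, "diffusion_estimate"),
            inherits(system, "membrane_system"),
            inherits(probe, "probe_spec"))
  if (d$kind != "rotational") {
    stop("pbc_correct_rotational() requires a rotational diffusion estimate",
         call. = FALSE)
  }
  if (direction == "to_infinite" && isTRUE(d$pbc_corrected)) {
    stop("estimate is already PBC-corrected", call. = FALSE)
  }
  if (direction == "to_periodic" && !isTRUE(d$pbc_corrected)) {
    stop("estimate is already a finite-box value", call. = FALSE)
  }
  frac <- probe$A_prot / system$L^2
  if (frac >= 1) {
    stop("probe cross-section A_prot must be smaller than the box area",
         call. = FALSE)
  }
  out <- d
  out$value <- if (direction == "to_infinite") {
    d$value / (1 - frac)
  } else {
    d$value * (1 - frac)
  }
  out$pbc_corrected <- direction == "to_infinite"
  .applicability_warn(out, applicability_warnings(d))
}
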