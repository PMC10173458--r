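## Saffman-Delbrueck hydrodynamics of a cylindrical inclusion spanning a thin
## viscous sheet (the membrane, 3D viscosity mu_m, thickness h) bounded on
## both sides by a less viscous solvent (mu_f).  Valid for probes much smaller
## than the SD length L_SD = h*mu_m/(2*mu_f); in practice R/L_SD < 0.1.

#' Hydrodynamic context of a membrane
#'
#' Bundles the quantities entering the Saffman-Delbrueck (SD) equations:
#' membrane shear viscosity, solvent shear viscosity, membrane thickness and
#' temperature.  Derived quantities (surface viscosity `eta = mu_m * h`, SD
#' length `L_SD = h * mu_m / (2 * mu_f)`) are computed on access via
#' [sd_length()] and never cached.
#'
#' @param mu_m membrane shear viscosity (mPa s).
#' @param mu_f solvent shear viscosity (mPa s).
#' @param h membrane thickness (nm).
#' @param T temperature (K).
#' @return an object of class `sd_context`.
#' @export
#' @examples
#' ctx <- sd_context(mu_m = 5, mu_f = 0.5, h = 4, T = 315)
#' sd_length(ctx)
sd_context <- function(mu_m, mu_f, h, T) {
  .check_positive(mu_m = mu_m, mu_f = mu_f, h = h, T = T)
  structure(list(mu_m = mu_m, mu_f = mu_f, h = h, T = T),
            class = "sd_context")
}

#' @export
print.sd_context <- function(x, ...) {
  cat(sprintf(
    "SD context: mu_m = %g mPa.s, mu_f = %g mPa.s, h = %g nm, T = %g K\n",
    x$mu_m, x$mu_f, x$h, x$T))
  cat(sprintf("  surface viscosity eta = %g mPa.s.nm,  L_SD = %g nm\n",
              x$mu_m * x$h, sd_length(x)))
  invisible(x)
}

#' Cylindrical probe specification
#'
#' @param R effective in-plane radius (nm), including any stably bound lipid
#'   shell.
#' @param label optional probe label.
#' @return an object of class `probe_spec` with derived cross-section area
#'   `A_prot = pi * R^2` (nm^2).
#' @export
probe_spec <- function(R, label = NA_character_) {
  .check_positive(R = R)
  structure(list(R = R, A_prot = pi * R^2, label = label),
            class = "probe_spec")
}

#' Saffman-Delbrueck length
#'
#' `L_SD = h * mu_m / (2 * mu_f)`, the length separating membrane-dominated
#' from solvent-dominated drag.  The SD diffusion formulas require
#' `R / L_SD < 0.1`.
#'
#' @param ctx an [sd_context()].
#' @return SD length in nm.
#' @export
sd_length <- function(ctx) {
  stopifnot(inherits(ctx, "sd_context"))
  ctx$h * ctx$mu_m / (2 * ctx$mu_f)
}

## shared validity check; returns character vector of warnings
.sd_applicability <- function(ctx, probe) {
  lsd <- sd_length(ctx)
  if (probe$R / lsd >= 0.1) {
    sprintf(paste0("probe radius R = %g nm is at or beyond the SD validity ",
                   "bound 0.1 * L_SD = %g nm (R/L_SD = %.3f)"),
            probe$R, 0.1 * lsd, probe$R / lsd)
  } else {
    character(0)
  }
}

#' Saffman-Delbrueck lateral diffusion coefficient
#'
#' Lateral diffusion coefficient of a cylindrical inclusion in an infinite
#' flat membrane:
#' `D_lat = kB*T / (4*pi*mu_m*h) * (ln(L_SD / R) - gamma)`,
#' with `gamma` the Euler-Mascheroni constant.  Linear in `T` at fixed
#' viscosities and strictly decreasing in both `R` and `mu_m`.
#'
#' @param ctx an [sd_context()].
#' @param probe a [probe_spec()].
#' @return lateral diffusion coefficient in cm^2/s.  If the probe is at or
#'   beyond the validity bound `R/L_SD >= 0.1` a structured warning is
#'   attached (see [applicability_warnings()]); the value is still returned.
#' @export
#' @examples
#' ctx <- sd_context(mu_m = 5, mu_f = 0.5, h = 4, T = 315)
#' sd_lateral_diffusion(ctx, probe_spec(R = 2))
sd_lateral_diffusion <- function(ctx, probe) {
  stopifnot(inherits(ctx, "sd_context"), inherits(probe, "probe_spec"))
  kc <- physical_constants
  lsd <- sd_length(ctx)
  arg <- lsd / probe$R
  if (arg <= exp(kc$euler_mascheroni)) {
    stop("probe radius exceeds the SD length; the lateral SD model has no ",
         "positive solution here", call. = FALSE)
  }
  d_si <- kc$boltzmann_constant * ctx$T /
    (4 * pi * .mPas(ctx$mu_m) * .nm(ctx$h)) *
    (log(arg) - kc$euler_mascheroni)               # m^2/s
  .applicability_warn(d_si * 1e4, .sd_applicability(ctx, probe))  # cm^2/s
}

#' Saffman-Delbrueck rotational diffusion coefficient
#'
#' Rotational diffusion about the membrane normal:
#' `D_rot = kB*T / (4*pi*mu_m*h*R^2)`.
#' Quadratic size dependence: doubling `R` quarters the value.
#'
#' @inheritParams sd_lateral_diffusion
#' @return rotational diffusion coefficient in rad^2/s, with validity
#'   warnings attached as for [sd_lateral_diffusion()].
#' @export
#' @examples
#' ctx <- sd_context(mu_m = 5, mu_f = 0.5, h = 4, T = 315)
#' sd_rotational_diffusion(ctx, probe_spec(R = 2))  # ~4.3e6 rad^2/s
sd_rotational_diffusion <- function(ctx, probe) {
  stopifnot(inherits(ctx, "sd_context"), inherits(probe, "probe_spec"))
  kc <- physical_constants
  d_si <- kc$boltzmann_constant * ctx$T /
    (4 * pi * .mPas(ctx$mu_m) * .nm(ctx$h) * .nm(probe$R)^2)   # rad^2/s
  .applicability_warn(d_si, .sd_applicability(ctx, probe))
}

#' Membrane system geometry
#'
#' Geometry and thermodynamic context of one simulated membrane patch in a
#' periodic box.  The box area `A_box = L^2` is derived, never stored.  The
#' flat-box condition required by the lateral finite-size correction is
#' `L >= 3 * L_z` where `L_z = h + 2*H` is the box extent along the membrane
#' normal.
#'
#' @param L lateral box edge (nm).
#' @param h membrane thickness (nm).
#' @param H solvent layer half-thickness (nm); the total solvent layer per
#'   periodic image is `2H`.
#' @param T temperature (K).
#' @param label composition label.
#' @param lipid_per_protein optional crowding descriptor.
#' @return an object of class `membrane_system`.
#' @export
membrane_system <- function(L, h, H, T, label = NA_character_,
                            lipid_per_protein = NA_real_) {
  .check_positive(L = L, h = h, H = H, T = T)
  structure(list(L = L, h = h, H = H, Lz = h + 2 * H, T = T,
                 label = label, lipid_per_protein = lipid_per_protein),
            class = "membrane_system")
}

#' @export
print.membrane_system <- function(x, ...) {
  cat(sprintf(
    "Membrane system%s: L = %g nm, h = %g nm, H = %g nm (L_z = %g nm), T = %g K\n",
    if (is.na(x$label)) "" else paste0(" '", x$label, "'"),
    x$L, x$h, x$H, x$Lz, x$T))
  if (!is_flat_box(x)) cat("  note: box is not flat (L < 3 L_z)\n")
  invisible(x)
}

#' @rdname membrane_system
#' @param system a `membrane_system`.
#' @return `is_flat_box()`: logical, whether `L >= 3 * L_z`.
#' @export
is_flat_box <- function(system) {
  stopifnot(inherits(system, "membrane_system"))
  system$L >= 3 * system$Lz
}
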