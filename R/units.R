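## Internal unit system: lengths in nm, times in ns, temperature in K,
## viscosity in mPa.s.  Conversion to SI happens only inside equation
## kernels.  Diffusion coefficients are reported in cm^2/s (lateral) and
## rad^2/s (rotational), the conventional units for membrane work.

#' Physical constants used throughout the package
#'
#' Fixed at package build; `euler_mascheroni` agrees with the reference value
#' to more than 9 digits.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{boltzmann_constant}{J/K, exact SI value 1.380649e-23.}
#'   \item{gas_constant}{J/(mol K), 8.31446.}
#'   \item{euler_mascheroni}{dimensionless, 0.5772156649...}
#' }
#' @export
#' @examples
#' physical_constants$euler_mascheroni
physical_constants <- list(
  boltzmann_constant = 1.380649e-23,
  gas_constant       = 8.31446261815324,
  euler_mascheroni   = 0.57721566490153286
)

## nm^2/ns -> cm^2/s: 1 nm^2 = 1e-14 cm^2, 1/ns = 1e9/s  => 1e-5
.NM2NS_TO_CM2S <- 1e-5
## rad^2/ns -> rad^2/s
.RAD2NS_TO_RAD2S <- 1e9

#' Convert a diffusion coefficient between trajectory and reporting units
#'
#' Trajectory analysis works in nm^2/ns (lateral) or rad^2/ns (rotational);
#' reported diffusion coefficients use cm^2/s and rad^2/s.  The two helpers
#' are exact inverses.
#'
#' @param x numeric, diffusion coefficient(s).
#' @param kind `"lateral"` or `"rotational"`.
#' @return numeric of the same length.
#' @export
#' @examples
#' d_traj_to_report(0.25, "lateral")   # 2.5e-6 cm^2/s
#' d_report_to_traj(d_traj_to_report(1, "rotational"), "rotational")
d_traj_to_report <- function(x, kind = c("lateral", "rotational")) {
  kind <- match.arg(kind)
  x * if (kind == "lateral") .NM2NS_TO_CM2S else .RAD2NS_TO_RAD2S
}

#' @rdname d_traj_to_report
#' @export
d_report_to_traj <- function(x, kind = c("lateral", "rotational")) {
  kind <- match.arg(kind)
  x / if (kind == "lateral") .NM2NS_TO_CM2S else .RAD2NS_TO_RAD2S
}

## internal SI helpers
.nm <- function(x) x * 1e-9          # nm -> m
.mPas <- function(x) x * 1e-3        # mPa.s -> Pa.s

.check_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      stop(sprintf("`%s` must be a positive number", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

## structured applicability warnings: attached to results as an attribute and
## raised as a classed condition so callers can choose warn vs fail policy.
.applicability_warn <- function(result, msgs) {
  if (length(msgs) == 0) return(result)
  old <- attr(result, "applicability")
  attr(result, "applicability") <- unique(c(old, msgs))
  for (m in msgs) {
    warning(warningCondition(m, class = "memvisc_applicability"))
  }
  result
}

#' Applicability warnings attached to a result
#'
#' Model functions near their validity edge (e.g. probe radius approaching
#' the Saffman-Delbrueck length, or a box that is not flat) attach structured
#' warnings instead of silently clamping.  This accessor returns them.
#'
#' @param x an object returned by a model or fitting function.
#' @return character vector of warnings (length 0 if none).
#' @export
applicability_warnings <- function(x) {
  w <- attr(x, "applicability")
  if (is.null(w)) character(0) else w
}
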