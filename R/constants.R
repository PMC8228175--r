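#' Physical constants used throughout the simulator
#'
#' Returns the set of fundamental constants the capacitance, carrier and
#' electrostatics formulas draw on.  The defaults are the rounded textbook
#' values the device model is parameterized with (e = 1.6e-19 C,
#' k = 1.3e-23 J/K, h = 6.6e-34 J s, eps0 = 8.854e-12 F/m); any of them can
#' be overridden for higher-precision work.
#'
#' The Dirac-channel formulas (Fermi level, quantum capacitance, gate-induced
#' carrier density) are physically stated in terms of the reduced Planck
#' constant hbar.  `planck_convention = "reduced"` (the default) uses
#' hbar = h / (2 pi) in those formulas; `"bare"` substitutes h itself, which
#' reproduces the literal typeset form found in some device-modelling
#' sources and is provided for cross-checking only.
#'
#' @param planck_convention `"reduced"` (default, physically standard) or
#'   `"bare"`; selects the constant used in Dirac-dispersion formulas.
#' @param e elementary charge (C).
#' @param k Boltzmann constant (J/K).
#' @param h Planck constant (J s).
#' @param eps0 vacuum permittivity (F/m).
#' @param avogadro Avogadro constant (1/mol), used by the ion-release model.
#' @return An object of class `physical_constants`: a list with fields `e`,
#'   `k`, `h`, `hbar`, `eps0`, `avogadro`, `planck_convention`, and
#'   `hbar_eff` (the constant actually used where hbar appears).
#' @examples
#' pc <- physical_constants()
#' pc$hbar / (pc$h / (2 * pi)) # 1
#' @export
physical_constants <- function(planck_convention = c("reduced", "bare"),
                               e = 1.6e-19,
                               k = 1.3e-23,
                               h = 6.6e-34,
                               eps0 = 8.854e-12,
                               avogadro = 6.022e23) {
  planck_convention <- match.arg(planck_convention)
  vals <- c(e = e, k = k, h = h, eps0 = eps0, avogadro = avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be finite and strictly positive")
  }
  hbar <- h / (2 * pi)
  structure(
    list(
      e = e, k = k, h = h, hbar = hbar, eps0 = eps0, avogadro = avogadro,
      planck_convention = planck_convention,
      hbar_eff = if (planck_convention == "reduced") hbar else h
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (", x$planck_convention, " Planck convention)\n",
      sep = "")
  cat(sprintf("  e    = %.4g C\n", x$e))
  cat(sprintf("  k    = %.4g J/K\n", x$k))
  cat(sprintf("  h    = %.4g J s (hbar = %.4g)\n", x$h, x$hbar))
  cat(sprintf("  eps0 = %.4g F/m\n", x$eps0))
  invisible(x)
}

# relative permittivity of the SiO2-equivalent gate dielectric
SIO2_EPS_R <- 3.9

# per-cm2 <-> per-m2 sheet-density conversion
PER_CM2_TO_PER_M2 <- 1e4
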