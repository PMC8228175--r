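#' LC tank readout
#'
#' The channel quantum capacitance is read out wirelessly as the resonant
#' frequency of an LC tank formed with a fixed inductor.  The default
#' inductance, 250 nH, sets a ~1 GHz resonance at the residual-capacitance
#' operating point.
#'
#' @param inductance inductance (H), > 0; default 250e-9.
#' @return Object of class `lc_readout`.
#' @export
lc_readout <- function(inductance = 250e-9) {
  if (!is.finite(inductance) || inductance <= 0) {
    stop("inductance must be strictly positive")
  }
  structure(list(inductance = inductance), class = "lc_readout")
}

#' Resonant frequency of the LC tank
#'
#' f = 1 / (2 pi sqrt(L C)).
#'
#' @param readout an [lc_readout] object (or a bare inductance in H).
#' @param capacitance capacitance (F), > 0; vectorized.
#' @return Frequency (Hz).
#' @examples
#' resonant_frequency(lc_readout(250e-9), 5.5e-12) # ~1.36e8 Hz
#' @export
resonant_frequency <- function(readout, capacitance) {
  L <- if (inherits(readout, "lc_readout")) readout$inductance else readout
  if (!is.numeric(L) || !is.finite(L) || L <= 0) {
    stop("inductance must be strictly positive")
  }
  if (any(!is.finite(capacitance)) || any(capacitance <= 0)) {
    stop("capacitance must be strictly positive")
  }
  1 / (2 * pi * sqrt(L * capacitance))
}

#' Carrier-concentration sweep of capacitance and resonant frequency
#'
#' Tabulates the degenerate quantum capacitance, tank resonant frequency and
#' tuning ratio over a grid of signed carrier concentrations (the grid is
#' given in the conventional per-cm^2 axis unit; the default spans
#' -3e13 ... +3e13 cm^-2 in 601 points).  At each grid point the effective
#' density is floored at the material's residual carrier density, which
#' regularizes the charge-neutrality point where the ideal C_Q (and hence
#' the frequency) would diverge.
#'
#' @param n_grid signed carrier concentrations (per cm^2).
#' @param material a [material_params] object.
#' @param geometry a [device_geometry] object; defaults to the material's.
#' @param readout an [lc_readout] object.
#' @param constants a [physical_constants] object.
#' @return A `data.frame` of class `frequency_sweep` with columns
#'   `n_per_cm2`, `cq_farad`, `freq_hz`, `tuning_ratio`.
#' @examples
#' sw <- frequency_sweep(material = material_params("silicene"))
#' range(sw$freq_hz)
#' @export
frequency_sweep <- function(n_grid = seq(-30e12, 30e12, length.out = 601),
                            material,
                            geometry = device_geometry_for(material),
                            readout = lc_readout(),
                            constants = physical_constants()) {
  stopifnot(inherits(material, "material_params"))
  if (length(n_grid) == 0) stop("carrier-concentration grid must be non-empty")
  n_m2 <- abs(n_grid) * PER_CM2_TO_PER_M2
  n_floor <- material$residual_carrier_density * PER_CM2_TO_PER_M2
  n_eff <- pmax(n_m2, n_floor)
  cq <- cq_degenerate(n_eff, material, geometry, constants)
  f <- resonant_frequency(readout, cq)
  out <- data.frame(
    n_per_cm2 = n_grid,
    cq_farad = cq,
    freq_hz = f,
    tuning_ratio = tuning_ratio(cq)
  )
  class(out) <- c("frequency_sweep", "data.frame")
  out
}

#' Tuning ratio of a capacitance series
#'
#' Dimensionless readout shift TR = 1 - sqrt(C_min / C): the relative
#' downward shift of the resonant frequency from the sweep's
#' minimum-capacitance point, since f is proportional to 1/sqrt(C).  Zero at
#' the minimum-capacitance row, monotone non-decreasing in C, bounded in
#' [0, 1).  This is the package's own pinned definition of the varactor-style
#' tuning metric.
#'
#' @param x a `frequency_sweep` data frame, or a numeric vector of
#'   capacitances (F).
#' @return Numeric vector of tuning ratios.
#' @examples
#' tuning_ratio(c(1e-12, 4e-12)) # 0, 0.5
#' @export
tuning_ratio <- function(x) {
  cq <- if (inherits(x, "frequency_sweep")) x$cq_farad else x
  if (length(cq) == 0) stop("empty capacitance series")
  if (any(!is.finite(cq)) || any(cq <= 0)) {
    stop("capacitances must be strictly positive")
  }
  1 - sqrt(min(cq) / cq)
}

#' Round to significant figures, half away from zero
#'
#' Reference values in the device literature are printed at two significant
#' figures; this helper reproduces that convention (round-half-away-from-zero,
#' unlike [signif()]'s banker-style rounding at ties).
#'
#' @param x numeric vector.
#' @param digits significant figures; default 2.
#' @export
round_sig <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  p <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^p + 0.5) * 10^p
  out
}
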