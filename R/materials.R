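#' Channel material parameters
#'
#' Constructs the parameter set for one 2D Dirac channel material.  Two
#' built-in presets, `"silicene"` and `"graphene"`, carry the simulation
#' parameters of the reference device (Fermi velocity, mobilities, band gap,
#' residual carrier density, native oxide thickness and gate length); any
#' field can be overridden.
#'
#' Residual carrier density is the electron-hole puddle floor that survives
#' at nominal zero doping; it regularizes the charge-neutrality point where
#' the ideal Dirac quantum capacitance would vanish.  The presets use the
#' clean-sample values 1e9 cm^-2 (silicene) and 1e10 cm^-2 (graphene),
#' consistent with silicene's lower charge density.
#'
#' @param name `"silicene"`, `"graphene"`, or any label when all numeric
#'   fields are supplied explicitly.
#' @param fermi_velocity Dirac Fermi velocity (m/s).
#' @param band_gap band gap (eV); informational, not used by the capacitance
#'   model.
#' @param intrinsic_mobility intrinsic carrier mobility (cm^2/V s).
#' @param field_effect_mobility field-effect mobility (cm^2/V s), used by the
#'   drain-current model.
#' @param residual_carrier_density residual sheet density (per cm^2).
#' @param oxide_thickness native equivalent oxide thickness (Angstrom).
#' @param gate_length gate length (micrometre).
#' @return Object of class `material_params`.
#' @examples
#' sil <- material_params("silicene")
#' gra <- material_params("graphene")
#' sil$fermi_velocity / gra$fermi_velocity
#' @export
material_params <- function(name = "silicene",
                            fermi_velocity = NULL,
                            band_gap = NULL,
                            intrinsic_mobility = NULL,
                            field_effect_mobility = NULL,
                            residual_carrier_density = NULL,
                            oxide_thickness = NULL,
                            gate_length = NULL) {
  presets <- list(
    silicene = list(
      fermi_velocity = 5.21e5, band_gap = 0.5,
      intrinsic_mobility = 1000, field_effect_mobility = 150,
      residual_carrier_density = 1e9,
      oxide_thickness = 6, gate_length = 1
    ),
    graphene = list(
      fermi_velocity = 1.1e6, band_gap = 0,
      intrinsic_mobility = 4000, field_effect_mobility = 1800,
      residual_carrier_density = 1e10,
      oxide_thickness = 5, gate_length = 0.2
    )
  )
  base <- presets[[tolower(name)]]
  if (is.null(base)) {
    base <- list(fermi_velocity = NA_real_, band_gap = 0,
                 intrinsic_mobility = NA_real_,
                 field_effect_mobility = NA_real_,
                 residual_carrier_density = NA_real_,
                 oxide_thickness = NA_real_, gate_length = NA_real_)
  }
  supplied <- list(
    fermi_velocity = fermi_velocity, band_gap = band_gap,
    intrinsic_mobility = intrinsic_mobility,
    field_effect_mobility = field_effect_mobility,
    residual_carrier_density = residual_carrier_density,
    oxide_thickness = oxide_thickness, gate_length = gate_length
  )
  for (f in names(supplied)) {
    if (!is.null(supplied[[f]])) base[[f]] <- as.numeric(supplied[[f]])
  }
  m <- c(list(name = tolower(name)), base)
  must_pos <- c("fermi_velocity", "intrinsic_mobility",
                "field_effect_mobility", "residual_carrier_density",
                "oxide_thickness", "gate_length")
  for (f in must_pos) {
    v <- m[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      stop(sprintf("material field '%s' must be a positive number", f))
    }
  }
  if (!is.finite(m$band_gap) || m$band_gap < 0) {
    stop("band_gap must be a non-negative number")
  }
  structure(m, class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Channel material:", x$name, "\n")
  cat(sprintf("  Fermi velocity        %.3g m/s\n", x$fermi_velocity))
  cat(sprintf("  band gap              %.3g eV\n", x$band_gap))
  cat(sprintf("  field-effect mobility %.3g cm^2/Vs\n",
              x$field_effect_mobility))
  cat(sprintf("  residual density      %.3g cm^-2\n",
              x$residual_carrier_density))
  cat(sprintf("  oxide thickness       %.3g A, gate length %.3g um\n",
              x$oxide_thickness, x$gate_length))
  invisible(x)
}

#' Fermi level of a Dirac channel at a given sheet density
#'
#' Inverts the Dirac carrier-density relation n = (E_F / (hbar v_F))^2 / pi:
#' E_F = sign(n) * hbar * v_F * sqrt(pi |n|).  The sign of `n` (electrons vs
#' holes) is carried onto the energy; the magnitude enters under the square
#' root.
#'
#' @param n signed sheet carrier density (per m^2); vectorized.
#' @param material a [material_params] object.
#' @param constants a [physical_constants] object.
#' @return Fermi energy (J), same length as `n`.
#' @export
fermi_level_from_n <- function(n, material, constants = physical_constants()) {
  stopifnot(inherits(material, "material_params"))
  sign(n) * constants$hbar_eff * material$fermi_velocity * sqrt(pi * abs(n))
}

#' Sheet density at a given Fermi level (inverse of [fermi_level_from_n])
#'
#' @param fermi_energy signed Fermi energy (J); vectorized.
#' @inheritParams fermi_level_from_n
#' @return signed sheet density (per m^2).
#' @export
n_from_fermi_level <- function(fermi_energy, material,
                               constants = physical_constants()) {
  stopifnot(inherits(material, "material_params"))
  hv <- constants$hbar_eff * material$fermi_velocity
  sign(fermi_energy) * (fermi_energy / hv)^2 / pi
}

#' Carrier state induced by a gate voltage plus external surface charge
#'
#' The channel sheet density decomposes into a gate-induced part
#' n_G = (e V / (hbar v_F))^2 / pi and an external surface-charge part n*
#' (for instance protons released by DNA hybridization); the net magnitude
#' is |n| = |n_G| + |n*|.  The sign of the gate voltage sets the carrier
#' polarity of the returned state.
#'
#' @param voltage gate voltage (V).
#' @param n_external external surface-charge sheet density n* (per m^2).
#' @param temperature channel temperature (K).
#' @inheritParams fermi_level_from_n
#' @return Object of class `carrier_state`: list with `n` (signed net, per
#'   m^2), `n_gate`, `n_external`, `fermi_energy` (J) and `temperature` (K).
#' @examples
#' st <- carrier_from_gate(0.1, 0, material_params("silicene"))
#' st$n_gate
#' @export
carrier_from_gate <- function(voltage, n_external = 0, material,
                              temperature = 300,
                              constants = physical_constants()) {
  stopifnot(inherits(material, "material_params"))
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive")
  }
  hv <- constants$hbar_eff * material$fermi_velocity
  n_gate <- (constants$e * abs(voltage) / hv)^2 / pi
  n_mag <- abs(n_gate) + abs(n_external)
  s <- if (voltage < 0) -1 else 1
  n <- s * n_mag
  structure(
    list(
      n = n, n_gate = s * n_gate, n_external = n_external,
      fermi_energy = fermi_level_from_n(n, material, constants),
      temperature = temperature
    ),
    class = "carrier_state"
  )
}

# resolve a geometry argument to an area in m^2: either a device_geometry
# object or a bare numeric area
resolve_area <- function(geometry) {
  if (inherits(geometry, "device_geometry")) return(area_m2(geometry))
  if (is.numeric(geometry) && length(geometry) == 1 && is.finite(geometry) &&
      geometry > 0) {
    return(geometry)
  }
  stop("geometry must be a device_geometry object or a positive area in m^2")
}

#' Finite-temperature quantum capacitance of a Dirac channel
#'
#' The thermally broadened quantum capacitance
#' \deqn{C_Q = \frac{2 e^2 k T}{\pi (\hbar v_F)^2}
#'       \ln\!\left[2\left(1 + \cosh\frac{E_F}{kT}\right)\right] \times A,}
#' where A is the active gate area.  Even in E_F; reduces to
#' (2 e^2 k T / (pi (hbar v_F)^2)) ln 4 per unit area at the charge
#' neutrality point, and to the degenerate form [cq_degenerate] when
#' E_F >> kT.
#'
#' @param fermi_energy Fermi energy E_F (J); vectorized.
#' @param temperature temperature (K), > 0.
#' @param material a [material_params] object.
#' @param geometry a [device_geometry] object, or a bare area in m^2 (pass 1
#'   for a per-unit-area value).
#' @param constants a [physical_constants] object.
#' @return Capacitance (F).
#' @export
cq_thermal <- function(fermi_energy, temperature = 300, material,
                       geometry = device_geometry_for(material),
                       constants = physical_constants()) {
  stopifnot(inherits(material, "material_params"))
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive")
  }
  area <- resolve_area(geometry)
  kT <- constants$k * temperature
  hv <- constants$hbar_eff * material$fermi_velocity
  x <- fermi_energy / kT
  # log(2 (1 + cosh x)) = log(4) + 2 log(cosh(x/2)), stable for large |x|
  lg <- log(4) + 2 * log_cosh(x / 2)
  2 * constants$e^2 * kT / (pi * hv^2) * lg * area
}

# log(cosh(x)) without overflow: |x| + log1p(exp(-2|x|)) - log 2
log_cosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

#' Degenerate-limit quantum capacitance of a Dirac channel
#'
#' The E_F >> kT limit of [cq_thermal]:
#' \deqn{C_Q = \frac{2 e^2}{\hbar v_F} \sqrt{\frac{|n|}{\pi}} \times A.}
#' Vanishes at n = 0 and is even in n; scales as sqrt(|n|).
#'
#' @param n signed sheet density (per m^2); vectorized.
#' @inheritParams cq_thermal
#' @return Capacitance (F).
#' @examples
#' cq_degenerate(1e16, material_params("silicene"), geometry = 1)
#' @export
cq_degenerate <- function(n, material,
                          geometry = device_geometry_for(material),
                          constants = physical_constants()) {
  stopifnot(inherits(material, "material_params"))
  area <- resolve_area(geometry)
  hv <- constants$hbar_eff * material$fermi_velocity
  2 * constants$e^2 / hv * sqrt(abs(n) / pi) * area
}
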