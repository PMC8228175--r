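#' Interdigitated gate geometry
#'
#' Geometry of the multi-finger gate stack.  The active area is
#' gate length x finger width x number of fingers, converted to m^2.
#'
#' @param gate_length_um gate length L (micrometre).
#' @param finger_width_um finger width W (micrometre); default 10.
#' @param n_fingers number of gate fingers N; default 200.
#' @param eot_nm equivalent oxide thickness (nm).
#' @return Object of class `device_geometry`.
#' @examples
#' g <- device_geometry(gate_length_um = 1, eot_nm = 0.6)
#' area_m2(g) # 2e-9 m^2
#' @export
device_geometry <- function(gate_length_um, finger_width_um = 10,
                            n_fingers = 200, eot_nm = 1) {
  vals <- c(gate_length_um = gate_length_um,
            finger_width_um = finger_width_um,
            n_fingers = n_fingers, eot_nm = eot_nm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be finite and strictly positive")
  }
  structure(as.list(vals), class = "device_geometry")
}

#' Default geometry for a channel material
#'
#' Builds the device geometry from the material's own gate length and native
#' oxide thickness (10 Angstrom = 1 nm), with the standard 200-finger,
#' 10 um finger-width gate.
#'
#' @param material a [material_params] object.
#' @inheritParams device_geometry
#' @export
device_geometry_for <- function(material, finger_width_um = 10,
                                n_fingers = 200) {
  stopifnot(inherits(material, "material_params"))
  device_geometry(gate_length_um = material$gate_length,
                  finger_width_um = finger_width_um,
                  n_fingers = n_fingers,
                  eot_nm = material$oxide_thickness / 10)
}

#' Active gate area (m^2)
#' @param geometry a [device_geometry] object.
#' @export
area_m2 <- function(geometry) {
  stopifnot(inherits(geometry, "device_geometry"))
  geometry$gate_length_um * 1e-6 * geometry$finger_width_um * 1e-6 *
    geometry$n_fingers
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf(
    "Gate geometry: L = %g um, W = %g um, N = %g fingers, EOT = %g nm\n",
    x$gate_length_um, x$finger_width_um, x$n_fingers, x$eot_nm))
  cat(sprintf("  active area %.4g m^2\n", area_m2(x)))
  invisible(x)
}

#' Series combination of two capacitors
#'
#' 1/C = 1/c1 + 1/c2, i.e. C = c1 c2 / (c1 + c2).  A zero capacitor forces
#' the series combination to zero; an infinite capacitor drops out, leaving
#' the other.
#'
#' @param c1,c2 capacitances (F), >= 0; vectorized.
#' @return Series capacitance (F).
#' @examples
#' series_pair(2e-12, 3e-12) # 1.2 pF
#' @export
series_pair <- function(c1, c2) {
  if (any(c1 < 0, na.rm = TRUE) || any(c2 < 0, na.rm = TRUE)) {
    stop("capacitances must be non-negative")
  }
  out <- ifelse(c1 == 0 | c2 == 0, 0,
                ifelse(is.infinite(c1), c2,
                       ifelse(is.infinite(c2), c1, c1 * c2 / (c1 + c2))))
  out
}

#' Four-capacitor ISFET network
#'
#' The lumped equivalent circuit of the electrolyte-gated stack: the FET
#' branch C_F = series(C_semi, C_OX) (substrate and oxide) in parallel with
#' the double-layer branch C_DL = series(C_elec, C_Q) (Stern layer and
#' channel quantum capacitance).
#'
#' @param c_semi semiconductor (substrate depletion) capacitance (F).
#' @param c_ox gate-oxide capacitance (F).
#' @param c_elec electrolyte (Stern/diffuse) capacitance (F).
#' @param c_q channel quantum capacitance (F).
#' @return Object of class `capacitor_network`.
#' @export
capacitor_network <- function(c_semi, c_ox, c_elec, c_q) {
  vals <- c(c_semi = c_semi, c_ox = c_ox, c_elec = c_elec, c_q = c_q)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("all capacitances must be non-negative")
  }
  structure(as.list(vals), class = "capacitor_network")
}

#' Double-layer branch capacitance C_DL = series(C_elec, C_Q)
#' @param net a [capacitor_network].
#' @export
c_double_layer <- function(net) {
  stopifnot(inherits(net, "capacitor_network"))
  series_pair(net$c_elec, net$c_q)
}

#' FET branch capacitance C_F = series(C_semi, C_OX)
#' @param net a [capacitor_network].
#' @export
c_fet <- function(net) {
  stopifnot(inherits(net, "capacitor_network"))
  series_pair(net$c_semi, net$c_ox)
}

#' Total ISFET capacitance C_ISFET = C_F + C_DL
#'
#' With C_OX >> C_semi and C_elec >> C_Q this reduces to C_semi + C_Q, so in
#' the usual operating regime the total is dominated by the channel quantum
#' capacitance.
#'
#' @param net a [capacitor_network].
#' @return Capacitance (F).
#' @export
total_isfet_capacitance <- function(net) {
  c_fet(net) + c_double_layer(net)
}

#' @export
print.capacitor_network <- function(x, ...) {
  cat(sprintf(
    "ISFET capacitor network (F): Csemi %.4g | Cox %.4g | Celec %.4g | Cq %.4g\n",
    x$c_semi, x$c_ox, x$c_elec, x$c_q))
  cat(sprintf("  C_F %.4g, C_DL %.4g, C_ISFET %.4g\n",
              c_fet(x), c_double_layer(x), total_isfet_capacitance(x)))
  invisible(x)
}

#' Gate-oxide capacitance from geometry
#'
#' C_OX = 3.9 eps0 / EOT x (L W N), the SiO2-equivalent parallel-plate
#' capacitance of the gate stack.  C_OX is inversely proportional to EOT,
#' so C_OX * EOT is constant across an EOT sweep.
#'
#' @param geometry a [device_geometry] object.
#' @param constants a [physical_constants] object.
#' @param per_area if `TRUE` return F/m^2 instead of F.
#' @return Capacitance (F, or F/m^2 when `per_area`).
#' @examples
#' g <- device_geometry(gate_length_um = 0.2, eot_nm = 1)
#' oxide_capacitance(g) # ~1.38e-11 F
#' @export
oxide_capacitance <- function(geometry, constants = physical_constants(),
                              per_area = FALSE) {
  stopifnot(inherits(geometry, "device_geometry"))
  if (geometry$eot_nm <= 0) stop("EOT must be positive")
  cpa <- SIO2_EPS_R * constants$eps0 / (geometry$eot_nm * 1e-9)
  if (per_area) cpa else cpa * area_m2(geometry)
}

#' Surface potential developed by a surface-charge change
#'
#' The electrochemical potential at the sensing surface produced by a change
#' in accumulated charge: psi = d_sigma / C_ISFET.  Linear in the charge.
#'
#' @param d_sigma accumulated surface charge change (C); vectorized.
#' @param c_isfet total ISFET capacitance (F), > 0.
#' @return Potential (V).
#' @export
surface_potential <- function(d_sigma, c_isfet) {
  if (any(!is.finite(c_isfet)) || any(c_isfet <= 0)) {
    stop("c_isfet must be strictly positive")
  }
  d_sigma / c_isfet
}

#' Threshold-voltage parameter set
#'
#' The electrochemical and semiconductor terms of the ISFET threshold
#' voltage: reference-electrode potential E_ref, solution surface-dipole
#' potential chi_sol, semiconductor work function phi_si, oxide charge Q_ox,
#' surface-state charge Q_ss and depletion charge Q_B (all per unit area),
#' and the Fermi potential phi_F.
#'
#' @param e_ref reference electrode potential (V).
#' @param chi_sol solution surface dipole potential (V).
#' @param phi_si semiconductor work function (V).
#' @param q_ox oxide accumulated charge (C/m^2).
#' @param q_ss surface-state charge (C/m^2).
#' @param q_b depletion charge (C/m^2).
#' @param phi_f Fermi potential (V).
#' @return Object of class `threshold_params`.
#' @export
threshold_params <- function(e_ref = 0, chi_sol = 0, phi_si = 0,
                             q_ox = 0, q_ss = 0, q_b = 0, phi_f = 0) {
  vals <- c(e_ref = e_ref, chi_sol = chi_sol, phi_si = phi_si,
            q_ox = q_ox, q_ss = q_ss, q_b = q_b, phi_f = phi_f)
  if (any(!is.finite(vals))) stop("all threshold parameters must be finite")
  structure(as.list(vals), class = "threshold_params")
}

#' ISFET threshold voltage
#'
#' V_th = E_ref - psi + chi_sol - phi_si - (Q_ox + Q_ss + Q_B)/C_OX' +
#' 2 phi_F, with C_OX' the per-area oxide capacitance.  The surface
#' potential psi enters with slope -1: any chemically induced potential
#' shifts the threshold down by the same amount.
#'
#' @param params a [threshold_params] object.
#' @param psi surface electrochemical potential (V); vectorized.
#' @param c_ox_per_area oxide capacitance per unit area (F/m^2), > 0.
#' @return Threshold voltage (V).
#' @export
threshold_voltage <- function(params, psi, c_ox_per_area) {
  stopifnot(inherits(params, "threshold_params"))
  if (any(!is.finite(c_ox_per_area)) || any(c_ox_per_area <= 0)) {
    stop("c_ox_per_area must be strictly positive")
  }
  params$e_ref - psi + params$chi_sol - params$phi_si -
    (params$q_ox + params$q_ss + params$q_b) / c_ox_per_area +
    2 * params$phi_f
}

#' Gate/drain bias point
#' @param v_gs gate-source voltage (V).
#' @param v_ds drain-source voltage (V).
#' @export
bias_point <- function(v_gs, v_ds) {
  if (!is.finite(v_gs) || !is.finite(v_ds)) stop("bias must be finite")
  structure(list(v_gs = v_gs, v_ds = v_ds), class = "bias_point")
}

#' Square-law ISFET drain current
#'
#' Triode-region current
#' I_DS = mu C_OX' (W/L) ((V_GS - V_th) V_DS - V_DS^2 / 2),
#' with W the total channel width (finger width x finger count).  Beyond
#' pinch-off (V_DS > V_GS - V_th) the current is clamped at its vertex
#' (saturation) value mu C_OX' (W/L) V_ov^2 / 2, and below threshold
#' (V_GS <= V_th) it is 0; both choices keep the curve continuous.
#'
#' @param bias a [bias_point] object.
#' @param v_th threshold voltage (V).
#' @param mobility field-effect mobility (cm^2/V s).
#' @param geometry a [device_geometry] object.
#' @param constants a [physical_constants] object.
#' @return Drain current (A).
#' @export
drain_current <- function(bias, v_th, mobility, geometry,
                          constants = physical_constants()) {
  stopifnot(inherits(bias, "bias_point"), inherits(geometry, "device_geometry"))
  if (!is.finite(mobility) || mobility <= 0) stop("mobility must be positive")
  mu_si <- mobility * 1e-4                       # cm^2/Vs -> m^2/Vs
  cox_pa <- oxide_capacitance(geometry, constants, per_area = TRUE)
  w_over_l <- geometry$finger_width_um * geometry$n_fingers /
    geometry$gate_length_um
  v_ov <- bias$v_gs - v_th
  if (v_ov <= 0 && bias$v_ds >= 0) return(0)
  pref <- mu_si * cox_pa * w_over_l
  v_ds_eff <- min(bias$v_ds, v_ov)               # saturation clamp
  pref * (v_ov * v_ds_eff - v_ds_eff^2 / 2)
}

#' Staged sensitivity of the sensing chain
#'
#' The relative drain-current response dI_DS / I_DS to a carrier-density
#' perturbation dn at the sensing surface, computed as the product of three
#' stages evaluated at the operating point:
#' \enumerate{
#'   \item charge: d_sigma = e A dn;
#'   \item gating: dV_gate = d_sigma / C_ISFET (the surface-potential shift,
#'     which lowers V_th one-for-one and so raises the effective gate
#'     overdrive);
#'   \item electronics: dI_DS = g_m dV_gate, with g_m the transconductance
#'     from the square-law current at the bias point (central finite
#'     difference).
#' }
#' The capacitor network is held fixed at the operating point: the
#' perturbation adds charge but its feedback on C_Q itself is a
#' second-order effect excluded from the staged definition.
#'
#' @param dn carrier-density perturbation (per m^2).
#' @param material a [material_params] object (supplies mobility).
#' @param geometry a [device_geometry] object.
#' @param net a [capacitor_network] at the operating point.
#' @param params a [threshold_params] object.
#' @param bias a [bias_point] object.
#' @param sigma0 baseline accumulated surface charge (C); default 0.
#' @param constants a [physical_constants] object.
#' @return List with the relative current change `relative_change`, the
#'   stage factors `d_sigma`, `d_v_gate`, `gm`, and the baseline current
#'   `i0`.
#' @export
sensitivity_chain <- function(dn, material, geometry, net, params, bias,
                              sigma0 = 0,
                              constants = physical_constants()) {
  stopifnot(inherits(net, "capacitor_network"))
  c_tot <- total_isfet_capacitance(net)
  cox_pa <- oxide_capacitance(geometry, constants, per_area = TRUE)
  psi0 <- surface_potential(sigma0, c_tot)
  vth0 <- threshold_voltage(params, psi0, cox_pa)
  i0 <- drain_current(bias, vth0, material$field_effect_mobility, geometry,
                      constants)
  if (i0 == 0) stop("baseline drain current is zero at this operating point")
  d_sigma <- constants$e * area_m2(geometry) * dn
  d_v_gate <- surface_potential(d_sigma, c_tot)
  h <- max(1e-6, abs(d_v_gate))                  # gm step (V)
  gm <- (drain_current(bias_point(bias$v_gs + h, bias$v_ds), vth0,
                       material$field_effect_mobility, geometry, constants) -
         drain_current(bias_point(bias$v_gs - h, bias$v_ds), vth0,
                       material$field_effect_mobility, geometry, constants)) /
    (2 * h)
  list(relative_change = d_v_gate * gm / i0,
       d_sigma = d_sigma, d_v_gate = d_v_gate, gm = gm, i0 = i0)
}

#' End-to-end current response to added surface charge
#'
#' The composed pipeline the staged sensitivity linearizes: a density
#' perturbation `dn` adds charge e A dn on top of `sigma0`, shifts the
#' surface potential and threshold voltage, and changes the square-law
#' drain current.  Returned as the relative current change (I - I0) / I0.
#'
#' @inheritParams sensitivity_chain
#' @export
current_response <- function(dn, material, geometry, net, params, bias,
                             sigma0 = 0,
                             constants = physical_constants()) {
  c_tot <- total_isfet_capacitance(net)
  cox_pa <- oxide_capacitance(geometry, constants, per_area = TRUE)
  ids <- function(sigma) {
    vth <- threshold_voltage(params, surface_potential(sigma, c_tot), cox_pa)
    drain_current(bias, vth, material$field_effect_mobility, geometry,
                  constants)
  }
  i0 <- ids(sigma0)
  if (i0 == 0) stop("baseline drain current is zero at this operating point")
  (ids(sigma0 + constants$e * area_m2(geometry) * dn) - i0) / i0
}
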