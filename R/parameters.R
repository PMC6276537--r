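# Parameter constructors. Internal unit system: time ms, voltage mV,
# concentration uM (glutamate mM), current pA, conductance nS. Rate constants
# quoted per second in the literature are stored per second and converted to
# per-ms in exactly one place (the integration step).

#' Physical constants used by the model
#'
#' Faraday's constant and the molar gas constant, used by the Mg2+ block
#' voltage dependence and the current-to-flux conversion of the calcium
#' balance.
#'
#' @format Named list with `F` (C/mol) and `R` (J/mol/K).
#' @export
spine_constants <- function() {
  list(F = 96487, R = 8.314)
}

#' Passive membrane parameters
#'
#' The spine membrane is a passive RC compartment producing EPSPs:
#' `tau_post * dV/dt = -(V - V_rest) + R_m * I_syn`.
#'
#' @param tau_post Membrane time constant (ms).
#' @param V_rest Resting potential (mV).
#' @param R_m Input resistance of the spine (megaohm). Spine input
#'   resistances are of gigaohm order; the default is part of the calibrated
#'   set.
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(tau_post = 8, V_rest = -70, R_m = 2960) {
  stopifnot(tau_post > 0, R_m > 0, is.finite(V_rest))
  structure(list(tau_post = tau_post, V_rest = V_rest, R_m = R_m),
            class = "membrane_params")
}

#' AMPA receptor parameters
#'
#' Two-state kinetic AMPAR (Destexhe-type): `dm/dt = alpha*T*(1-m) - beta*m`
#' with glutamate concentration `T`, ohmic current
#' `I = g_AMPA * m * (V - V_AMPA)`, and CaMKII-dependent conductance
#' `g_AMPA = g_AMPA0 * (1 + 1/(1 + exp(-(Ph - P_half)/k_half)))`, so the
#' conductance runs from `g_AMPA0` (no phosphorylation) to `2*g_AMPA0`
#' (saturation) with midpoint `1.5*g_AMPA0` at `Ph = P_half`.
#'
#' @param g_AMPA0 Baseline conductance (nS).
#' @param V_AMPA Reversal potential (mV).
#' @param alpha Opening rate (per mM per ms).
#' @param beta Closing rate (per ms).
#' @param P_half Phosphorylated-CaMKII level at half-maximal enhancement (uM).
#' @param k_half Sigmoid slope (uM).
#' @return An object of class `ampar_params`.
#' @export
ampar_params <- function(g_AMPA0 = 0.4, V_AMPA = 0, alpha = 1.1, beta = 0.19,
                         P_half = 40, k_half = 0.4) {
  stopifnot(g_AMPA0 > 0, alpha > 0, beta > 0, k_half > 0)
  structure(list(g_AMPA0 = g_AMPA0, V_AMPA = V_AMPA, alpha = alpha,
                 beta = beta, P_half = P_half, k_half = k_half),
            class = "ampar_params")
}

#' NMDA receptor parameters
#'
#' Two-state kinetic NMDAR with voltage-dependent Mg2+ block and an
#' opioid-sensitive conductance. Total conductance is
#' `g_NMDA = g_VI + coeff * 0.15 * s(Op) + g_VD`, where `s(Op)` is the opioid
#' saturation function (see [opioid_saturation()]) and the voltage-dependent
#' part relaxes as `dg_VD/dt = (max(k_slope*(V - V0), 0) - g_VD)/tau_g`.
#' The Mg2+ block factor is Woodhull-type,
#' `Mg = 1/(1 + Mg_out * exp(-z*(delta + 0.1*s)*F*V/(R*T)) / (k0 + 15.58*s))`.
#'
#' @param V_NMDA Reversal potential (mV).
#' @param alpha Opening rate (per mM per ms).
#' @param beta Closing rate (per ms).
#' @param g_VI Voltage-independent conductance (nS).
#' @param tau_g Relaxation time constant of `g_VD` (ms).
#' @param k_slope Linear gain of the `g_VD` target per mV above `V0` (nS/mV).
#' @param V0 Offset potential for the `g_VD` target (mV).
#' @param Mg_out External Mg2+ concentration (mM).
#' @param k0 Mg2+ affinity constant at zero opioid (mM).
#' @param z Charge of the blocking ion.
#' @param delta Electrical distance of the blocking site (0..1).
#' @param Temp Absolute temperature (K).
#' @return An object of class `nmdar_params`.
#' @export
nmdar_params <- function(V_NMDA = 0, alpha = 0.164, beta = 0.0066,
                         g_VI = 0.0075, tau_g = 150, k_slope = 0.212,
                         V0 = -56, Mg_out = 1, k0 = 9.83, z = 2,
                         delta = 0.415, Temp = 308) {
  stopifnot(tau_g > 0, Mg_out >= 0, delta >= 0, delta <= 1, Temp > 0,
            alpha > 0, beta > 0, g_VI >= 0, k0 > 0)
  structure(list(V_NMDA = V_NMDA, alpha = alpha, beta = beta, g_VI = g_VI,
                 tau_g = tau_g, k_slope = k_slope, V0 = V0, Mg_out = Mg_out,
                 k0 = k0, z = z, delta = delta, Temp = Temp),
            class = "nmdar_params")
}

#' Voltage-gated calcium channel parameters
#'
#' A pool of `N` high-voltage-activated channels; the number open at each
#' integration step is a binomial draw `B(N, P_open(V))` with a logistic
#' opening probability `P_open(V) = 1/(1 + exp(-(V - Vh_open)/k_open))`.
#' Each open channel passes `g_R * (V - V_R)`.
#'
#' @param g_R Single-channel conductance (pS).
#' @param V_R Reversal potential (mV).
#' @param N Number of channels (non-negative integer).
#' @param Vh_open Half-activation voltage (mV).
#' @param k_open Activation slope (mV).
#' @return An object of class `vgcc_params`.
#' @export
vgcc_params <- function(g_R = 15, V_R = 27.4, N = 80, Vh_open = -49.2,
                        k_open = 1.39) {
  stopifnot(N >= 0, N == round(N), g_R >= 0, k_open > 0)
  structure(list(g_R = g_R, V_R = V_R, N = as.integer(N),
                 Vh_open = Vh_open, k_open = k_open),
            class = "vgcc_params")
}

#' Spine calcium-handling parameters
#'
#' Calcium balance with the rapid-buffer approximation:
#' `dc/dt = f(c)/(1 + theta(c))` with
#' `f(c) = -(eta*I_AMPA + gamma*I_NMDA + I_R)/(Z_ca*F*V_spine) - S_pump(c)`,
#' `theta(c) = b_t*K_endo/(K_endo + c)^2`, and a linear pump
#' `S_pump = K_s*(c - c_rest)`.
#'
#' @param eta Fraction of AMPAR current carried by calcium (dimensionless).
#' @param gamma Fraction of NMDAR current carried by calcium (dimensionless).
#' @param Z_ca Calcium valence.
#' @param V_spine Spine volume (um^3).
#' @param b_t Total endogenous buffer concentration (uM).
#' @param K_endo Endogenous buffer affinity (uM).
#' @param K_s Maximum pump efflux rate (per s).
#' @param c_rest Resting calcium concentration (uM).
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(eta = 0.012, gamma = 0.06, Z_ca = 2,
                           V_spine = 0.9048, b_t = 200, K_endo = 10,
                           K_s = 100, c_rest = 0.1) {
  stopifnot(eta >= 0, gamma >= 0, Z_ca > 0, V_spine > 0, b_t >= 0,
            K_endo > 0, K_s >= 0, c_rest >= 0)
  structure(list(eta = eta, gamma = gamma, Z_ca = Z_ca, V_spine = V_spine,
                 b_t = b_t, K_endo = K_endo, K_s = K_s, c_rest = c_rest),
            class = "calcium_params")
}

#' CaMKII/PP1/inhibitor-1 cascade parameters
#'
#' The holoenzyme is tracked as eleven species P0..P10 (i-fold phosphorylated
#' CaMKII, uM). Calcium drives initial phosphorylation (v1, uM/s) and
#' autophosphorylation (v2, per s); active PP1 (`ep`) dephosphorylates (v3,
#' per s) and is itself inactivated by phosphorylated inhibitor-1 (I1P),
#' which PKA produces and calcineurin removes in a calcium-dependent way.
#' All rate constants are quoted per second.
#'
#' @param e_p0 Total PP1 concentration (uM).
#' @param I_0 Free inhibitor-1 concentration (uM).
#' @param k3 PP1-I1P association rate (per uM per s).
#' @param k4 PP1-I1P dissociation rate (per s).
#' @param v_CaN Calcineurin-mediated I1P dephosphorylation rate (per s).
#' @param v_PKA PKA-mediated I1 phosphorylation rate (uM/s per uM of I1,
#'   applied to `I_0`).
#' @param K_H2 Calcium Hill constant of calcineurin activation (uM).
#' @param k1 PP1-dependent regulation rate of CaMKII phosphorylation (per s).
#' @param K_H1 Calcium Hill constant of CaMKII activation (uM).
#' @param K_M Michaelis constant of dephosphorylation (uM).
#' @param k2 Catalytic constant of dephosphorylation (per s).
#' @param camkii_total Total CaMKII subunit concentration (uM); the initial
#'   condition puts it all in P0. Must exceed the AMPAR sigmoid midpoint for
#'   LTP to be expressible.
#' @return An object of class `cascade_params`.
#' @export
cascade_params <- function(e_p0 = 0.1, I_0 = 0.1, k3 = 1, k4 = 1e-3,
                           v_CaN = 2, v_PKA = 0.45, K_H2 = 0.7, k1 = 0.5,
                           K_H1 = 4, K_M = 20, k2 = 10, camkii_total = 100) {
  stopifnot(e_p0 > 0, I_0 >= 0, k3 > 0, k4 > 0, v_CaN > 0, v_PKA >= 0,
            K_H2 > 0, k1 > 0, K_H1 > 0, K_M > 0, k2 > 0, camkii_total > 0)
  structure(list(e_p0 = e_p0, I_0 = I_0, k3 = k3, k4 = k4, v_CaN = v_CaN,
                 v_PKA = v_PKA, K_H2 = K_H2, k1 = k1, K_H1 = K_H1, K_M = K_M,
                 k2 = k2, camkii_total = camkii_total),
            class = "cascade_params")
}

#' Full model parameter set
#'
#' Bundles the six parameter groups. Defaults are the package's canonical
#' calibrated set: the constants fixed by the model definition are used
#' verbatim,
#' the remainder were calibrated once so that the reference contrasts hold
#' (see the methods vignette) and are version-pinned in
#' `inst/extdata/default_config.yaml`.
#'
#' @param membrane,ampar,nmdar,vgcc,calcium,cascade Parameter group objects;
#'   see the individual constructors.
#' @return An object of class `spine_params`.
#' @examples
#' p <- spine_params()
#' p$ampar$g_AMPA0
#' @export
spine_params <- function(membrane = membrane_params(),
                         ampar = ampar_params(),
                         nmdar = nmdar_params(),
                         vgcc = vgcc_params(),
                         calcium = calcium_params(),
                         cascade = cascade_params()) {
  stopifnot(inherits(membrane, "membrane_params"),
            inherits(ampar, "ampar_params"),
            inherits(nmdar, "nmdar_params"),
            inherits(vgcc, "vgcc_params"),
            inherits(calcium, "calcium_params"),
            inherits(cascade, "cascade_params"))
  if (cascade$camkii_total <= ampar$P_half)
    stop("camkii_total must exceed the AMPAR sigmoid midpoint P_half, ",
         "otherwise LTP is unreachable", call. = FALSE)
  structure(list(membrane = membrane, ampar = ampar, nmdar = nmdar,
                 vgcc = vgcc, calcium = calcium, cascade = cascade),
            class = "spine_params")
}

#' @export
print.spine_params <- function(x, ...) {
  cat("Spine model parameters\n")
  for (grp in names(x)) {
    vals <- unlist(x[[grp]])
    cat(sprintf("  %-9s %s\n", paste0(grp, ":"),
                paste(sprintf("%s=%g", names(vals), vals), collapse = ", ")))
  }
  invisible(x)
}

#' Opioid condition
#'
#' Describes the opioid concentration in the synapse and which of the three
#' modelled mechanisms are active. The three toggles reproduce the
#' mechanism-knockout conditions of the five-condition comparison:
#' `conductance_effect = FALSE` removes the opioid increment to NMDAR
#' conductance ("CK = 0"), `mg_effect = FALSE` freezes the Mg2+ block at its
#' opioid-free form ("CMg = 0"), and `vgcc = FALSE` zeroes the VGCC current
#' ("Icr = 0"). `nmdar_coeff` and `vgcc_coeff` scale the opioid conductance
#' term and the VGCC current for the sweep experiments.
#'
#' @param Op Opioid concentration (uM).
#' @param conductance_effect Logical; opioid effect on NMDAR conductance.
#' @param mg_effect Logical; opioid effect on the Mg2+ block.
#' @param vgcc Logical; VGCC current enabled.
#' @param nmdar_coeff Multiplier on the opioid conductance term.
#' @param vgcc_coeff Multiplier on the VGCC current.
#' @param form Opioid saturation form, `"saturating"` (default; increasing
#'   with Op, zero at Op = 0) or `"printed"` (the literal decreasing form of
#'   reciprocal dose factor, decreasing in Op). See [opioid_saturation()].
#' @return An object of class `opioid_condition`.
#' @examples
#' normal <- opioid_condition(Op = 0)
#' pathological <- opioid_condition(Op = 1)
#' ck0 <- opioid_condition(Op = 1, conductance_effect = FALSE)
#' @export
opioid_condition <- function(Op = 0, conductance_effect = TRUE,
                             mg_effect = TRUE, vgcc = TRUE,
                             nmdar_coeff = 1, vgcc_coeff = 1,
                             form = c("saturating", "printed")) {
  form <- match.arg(form)
  stopifnot(Op >= 0, nmdar_coeff >= 0, vgcc_coeff >= 0,
            is.logical(conductance_effect), is.logical(mg_effect),
            is.logical(vgcc))
  structure(list(Op = Op, conductance_effect = conductance_effect,
                 mg_effect = mg_effect, vgcc = vgcc,
                 nmdar_coeff = nmdar_coeff, vgcc_coeff = vgcc_coeff,
                 form = form),
            class = "opioid_condition")
}

#' @export
print.opioid_condition <- function(x, ...) {
  cat(sprintf(
    "Opioid condition: Op = %g uM (%s form)\n", x$Op, x$form))
  cat(sprintf("  conductance effect: %s (coeff %g)\n",
              x$conductance_effect, x$nmdar_coeff))
  cat(sprintf("  Mg2+ block effect:  %s\n", x$mg_effect))
  cat(sprintf("  VGCC current:       %s (coeff %g)\n", x$vgcc, x$vgcc_coeff))
  invisible(x)
}

#' Simulation settings
#'
#' @param dt Euler step size (ms).
#' @param t_end Simulation horizon (s).
#' @param seed Integer RNG seed, or `NULL` to leave the RNG state untouched.
#' @param record_stride Number of Euler steps between recorded samples.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.05, t_end = 10, seed = NULL,
                       record_stride = 20) {
  stopifnot(dt > 0, t_end > 0, record_stride >= 1,
            record_stride == round(record_stride))
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(dt = dt, t_end = t_end, seed = seed,
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}
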