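# Membrane, receptor, channel and calcium right-hand sides. These R
# implementations are the reference definitions of each model term; the
# compiled engine (src/engine.cpp) implements the identical arithmetic and is
# cross-checked against them in the test suite.

#' Opioid saturation function
#'
#' The dimensionless dose factor s(Op) shared by the three opioid-dependent
#' terms of the model (Mg2+ affinity shift, electrical-distance shift, and
#' NMDAR conductance increment, with magnitudes 15.58, 0.1 and 0.15 at
#' saturation).
#'
#' The default `"saturating"` form is
#' `s(Op) = Op^1.2 / (Op^1.2 + 0.1^1.2)` (half-effect at 0.1 uM): it is zero
#' without opioid, increases monotonically, saturates at 1, and is ~0.94 at
#' the reference dose of 1 uM, matching the mechanism direction (opioids
#' weaken the Mg2+ block and enhance NMDAR conductance). The `"printed"` form
#' `s(Op) = 1/(1 + (0.1*Op)^1.2)` is the literal transcription of the source
#' equations; it decreases with Op (full effect at Op = 0) and is retained
#' for comparison only.
#'
#' @param Op Opioid concentration (uM); vectorized.
#' @param form `"saturating"` (default) or `"printed"`.
#' @return Saturation factor(s) in `[0, 1]`.
#' @export
opioid_saturation <- function(Op, form = c("saturating", "printed")) {
  form <- match.arg(form)
  if (any(Op < 0)) stop("Op must be non-negative", call. = FALSE)
  if (form == "saturating") {
    x <- Op^1.2
    x / (x + 0.1^1.2)
  } else {
    1 / (1 + (0.1 * Op)^1.2)
  }
}

#' Mg2+ block factor of the NMDA receptor
#'
#' Woodhull-type voltage-dependent block with opioid-sensitive affinity and
#' electrical distance:
#' `Mg = 1 / (1 + Mg_out * exp(-z*(delta + 0.1*s)*F*V/(R*T)) / (k0 + 15.58*s))`
#' where `s = opioid_saturation(Op)`. The factor lies in (0, 1], is strictly
#' increasing in V (block relieved by depolarization), and reduces to the
#' standard opioid-free expression at Op = 0. When the condition's
#' `mg_effect` toggle is off, `s` is frozen at its Op = 0 value.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param Op Opioid concentration (uM).
#' @param p An [nmdar_params()] object.
#' @param mg_effect Logical; if `FALSE` the opioid dependence is frozen at
#'   Op = 0.
#' @param form Opioid saturation form; see [opioid_saturation()].
#' @return Blocking factor(s) in (0, 1].
#' @export
mg_block <- function(V, Op = 0, p = nmdar_params(), mg_effect = TRUE,
                     form = c("saturating", "printed")) {
  form <- match.arg(form)
  cst <- spine_constants()
  s <- opioid_saturation(if (mg_effect) Op else 0, form)
  k_eff <- p$k0 + 15.58 * s
  delta_eff <- p$delta + 0.1 * s
  # F*V/(R*T) with V in mV -> factor 1e-3 to volts
  expo <- -p$z * delta_eff * cst$F * V * 1e-3 / (cst$R * p$Temp)
  1 / (1 + p$Mg_out * exp(expo) / k_eff)
}

#' Total NMDA receptor conductance
#'
#' `g_NMDA = g_VI + nmdar_coeff * 0.15 * s(Op) + g_VD`. The opioid increment
#' is zero at Op = 0, non-decreasing in Op, saturates at
#' `0.15 * nmdar_coeff` nS, and is identically zero when the condition's
#' `conductance_effect` toggle is off (the "CK = 0" knockout).
#'
#' @param g_VD Voltage-dependent conductance component (nS).
#' @param Op Opioid concentration (uM).
#' @param cond An [opioid_condition()]; supplies the toggle, coefficient and
#'   saturation form.
#' @param p An [nmdar_params()] object.
#' @return Conductance (nS).
#' @export
nmdar_conductance <- function(g_VD, Op = cond$Op, cond = opioid_condition(),
                              p = nmdar_params()) {
  stopifnot(all(is.finite(g_VD)))
  term <- if (cond$conductance_effect)
    cond$nmdar_coeff * 0.15 * opioid_saturation(Op, cond$form)
  else 0
  g <- p$g_VI + term + g_VD
  if (any(g < 0))
    stop("negative NMDAR conductance: model-consistency error", call. = FALSE)
  g
}

#' Relaxation derivative of the voltage-dependent NMDAR conductance
#'
#' `dg_VD/dt = (g_inf - g_VD)/tau_g` with the target
#' `g_inf = max(k_slope * (V - V0), 0)`; the floor keeps the conductance
#' target non-negative below `V0`.
#'
#' @param g_VD Current value (nS).
#' @param V Membrane potential (mV).
#' @param p An [nmdar_params()] object.
#' @return Derivative (nS/ms).
#' @export
g_vd_derivative <- function(g_VD, V, p = nmdar_params()) {
  g_inf <- pmax(p$k_slope * (V - p$V0), 0)
  (g_inf - g_VD) / p$tau_g
}

#' Two-state receptor gating derivative
#'
#' `dm/dt = alpha * T * (1 - m) - beta * m`, shared by the AMPAR and NMDAR
#' gating variables (`T` is the glutamate concentration).
#'
#' @param m Gating variable (dimensionless, in `[0, 1]`).
#' @param g_pre Glutamate concentration (mM).
#' @param alpha Opening rate (per mM per ms).
#' @param beta Closing rate (per ms).
#' @return Derivative (per ms).
#' @export
receptor_gating_derivative <- function(m, g_pre, alpha, beta) {
  stopifnot(all(m >= 0), all(m <= 1), all(g_pre >= 0))
  alpha * g_pre * (1 - m) - beta * m
}

#' AMPA receptor current
#'
#' `I_AMPA = g_AMPA * m * (V - V_AMPA)` (pA); inward (negative) below the
#' reversal potential.
#'
#' @param V Membrane potential (mV).
#' @param m_AMPA Gating variable.
#' @param g_AMPA Current conductance (nS).
#' @param p An [ampar_params()] object (supplies the reversal potential).
#' @return Current (pA).
#' @export
ampar_current <- function(V, m_AMPA, g_AMPA, p = ampar_params()) {
  g_AMPA * m_AMPA * (V - p$V_AMPA)
}

#' NMDA receptor current
#'
#' `I_NMDA = g_NMDA * m_NMDA * Mg * (V - V_NMDA)` (pA); the product form
#' vanishes when any factor is zero.
#'
#' @param V Membrane potential (mV).
#' @param m_NMDA Gating variable.
#' @param g_NMDA Total conductance (nS); see [nmdar_conductance()].
#' @param Mg Mg2+ block factor; see [mg_block()].
#' @param p An [nmdar_params()] object (supplies the reversal potential).
#' @return Current (pA).
#' @export
nmdar_current <- function(V, m_NMDA, g_NMDA, Mg, p = nmdar_params()) {
  g_NMDA * m_NMDA * Mg * (V - p$V_NMDA)
}

#' AMPAR conductance as a function of phosphorylated CaMKII
#'
#' `g_AMPA = g_AMPA0 * (1 + 1/(1 + exp(-(Ph - P_half)/k_half)))`: strictly
#' increasing, `g_AMPA0` at Ph = 0 (to within ~1e-43 for the default
#' midpoint), `1.5*g_AMPA0` at the midpoint, `2*g_AMPA0` at saturation.
#'
#' @param phospho Phosphorylated CaMKII (uM); vectorized.
#' @param p An [ampar_params()] object.
#' @return Conductance (nS).
#' @export
ampar_conductance_from_camkii <- function(phospho, p = ampar_params()) {
  p$g_AMPA0 * (1 + stats::plogis((phospho - p$P_half) / p$k_half))
}

#' VGCC opening probability
#'
#' Logistic high-voltage activation
#' `P_open(V) = 1/(1 + exp(-(V - Vh_open)/k_open))`; effectively zero at
#' resting and ordinary EPSP voltages with the default half-activation.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param p A [vgcc_params()] object.
#' @return Opening probability in (0, 1).
#' @export
vgcc_open_probability <- function(V, p = vgcc_params()) {
  stats::plogis((V - p$Vh_open) / p$k_open)
}

#' Stochastic VGCC current
#'
#' Draws the number of open channels `n ~ Binomial(N, P_open(V))` from R's
#' RNG stream and returns `vgcc_coeff * g_R * n * (V - V_R)` in pA (`g_R` is
#' converted from pS). With the condition's `vgcc` toggle off the current is
#' exactly 0 and no draw is made.
#'
#' @param V Membrane potential (mV); scalar.
#' @param cond An [opioid_condition()].
#' @param p A [vgcc_params()] object.
#' @return Current (pA).
#' @export
vgcc_current <- function(V, cond = opioid_condition(), p = vgcc_params()) {
  if (!cond$vgcc || cond$vgcc_coeff == 0) return(0)
  n_open <- stats::rbinom(1L, p$N, vgcc_open_probability(V, p))
  cond$vgcc_coeff * (p$g_R * 1e-3) * n_open * (V - p$V_R)
}

#' Calcium pump rate
#'
#' Linear pump `S_pump = K_s * (c - c_rest)`, returned per millisecond;
#' negative below rest (the pump is symmetric around the resting level).
#'
#' @param c Calcium concentration (uM); vectorized.
#' @param p A [calcium_params()] object.
#' @return Pump rate (uM/ms).
#' @export
pump_rate <- function(c, p = calcium_params()) {
  p$K_s * 1e-3 * (c - p$c_rest)
}

# uM/ms of free-calcium change per pA of calcium-carrying current:
# I [pA] = 1e-12 C/s; / (Z*F) -> mol/s; / (V_spine um^3 = 1e-15 L) -> M/s;
# *1e6 -> uM/s; *1e-3 -> uM/ms.
calcium_flux_per_pA <- function(p) {
  cst <- spine_constants()
  1e-12 / (p$Z_ca * cst$F * p$V_spine * 1e-15) * 1e6 * 1e-3
}

#' Calcium balance derivative
#'
#' Rapid-buffer calcium dynamics:
#' `dc/dt = f(c)/(1 + theta(c))` with
#' `f(c) = -(eta*I_AMPA + gamma*I_NMDA + I_R)/(Z_ca*F*V_spine) - S_pump(c)`
#' and `theta(c) = b_t*K_endo/(K_endo + c)^2`. Inward (negative) currents
#' raise calcium. The pA -> uM/ms conversion through Faraday's constant and
#' the spine volume is internal.
#'
#' @param c Calcium concentration (uM).
#' @param I_AMPA,I_NMDA,I_R Currents (pA).
#' @param p A [calcium_params()] object.
#' @return Derivative (uM/ms).
#' @export
calcium_derivative <- function(c, I_AMPA, I_NMDA, I_R, p = calcium_params()) {
  if (any(c < 0))
    stop("negative calcium concentration: state-corruption error",
         call. = FALSE)
  kappa <- calcium_flux_per_pA(p)
  f <- -(p$eta * I_AMPA + p$gamma * I_NMDA + I_R) * kappa - pump_rate(c, p)
  theta <- p$b_t * p$K_endo / (p$K_endo + c)^2
  f / (1 + theta)
}

#' Passive membrane derivative
#'
#' `dV/dt = (-(V - V_rest) + R_m * I_syn)/tau_post` with the synaptic current
#' `I_syn = -(I_AMPA + I_NMDA)`; `R_m` (megaohm) times pA gives microvolts,
#' converted internally to mV. The VGCC current feeds only the calcium pool,
#' not the membrane equation.
#'
#' @param V Membrane potential (mV).
#' @param I_AMPA,I_NMDA Receptor currents (pA).
#' @param p A [membrane_params()] object.
#' @return Derivative (mV/ms).
#' @export
membrane_derivative <- function(V, I_AMPA, I_NMDA, p = membrane_params()) {
  I_syn <- -(I_AMPA + I_NMDA)
  (-(V - p$V_rest) + p$R_m * I_syn * 1e-3) / p$tau_post
}
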