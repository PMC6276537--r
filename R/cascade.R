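# Calcium-driven CaMKII phosphorylation ladder with PP1/inhibitor-1 control.
# All cascade rate constants are per second; the engine converts to per-ms
# when stepping.

# Forward autophosphorylation ladder coefficients for transitions
# P1->P2 ... P9->P10 (P0->P1 goes through v1). The symmetric profile reflects
# the number of active-neighbour configurations of the ring-shaped holoenzyme.
ladder_coefficients <- function() c(1, 1.8, 2.3, 2.7, 2.8, 2.7, 2.3, 1.8, 1)

#' Cascade reaction rates
#'
#' Computes the three lumped rates of the CaMKII/PP1 switch at a given
#' calcium level:
#' \describe{
#'   \item{v1}{initial phosphorylation, `10*k1*(c/K_H1)^8*P0/(1+(c/K_H1)^4)^2`
#'     (uM/s);}
#'   \item{v2}{autophosphorylation, `k1*(c/K_H1)^4/(1+(c/K_H1)^4)` (per s);}
#'   \item{v3}{PP1-mediated dephosphorylation,
#'     `k2*ep/(K_M + sum(i*P_i))` (per s).}
#' }
#'
#' @param c_post Calcium concentration (uM).
#' @param state A [cascade_state()] list with `P` (P0..P10), `ep`, `I1P`.
#' @param p A [cascade_params()] object.
#' @return Named list `v1`, `v2`, `v3` (all non-negative).
#' @export
cascade_rates <- function(c_post, state, p = cascade_params()) {
  stopifnot(c_post >= 0)
  r4 <- (c_post / p$K_H1)^4
  r8 <- r4^2
  v1 <- 10 * p$k1 * r8 * state$P[1] / (1 + r4)^2
  v2 <- p$k1 * r4 / (1 + r4)
  weighted <- sum((1:10) * state$P[2:11])
  v3 <- p$k2 * state$ep / (p$K_M + weighted)
  list(v1 = v1, v2 = v2, v3 = v3)
}

#' Cascade state constructor
#'
#' @param P Numeric vector of 11 concentrations P0..P10 (uM).
#' @param ep Active (uninhibited) PP1 (uM).
#' @param I1P Free phosphorylated inhibitor-1 (uM).
#' @return A list of class `cascade_state`.
#' @export
cascade_state <- function(P, ep, I1P) {
  stopifnot(length(P) == 11, all(P >= 0), ep >= 0, I1P >= 0)
  structure(list(P = as.numeric(P), ep = ep, I1P = I1P),
            class = "cascade_state")
}

#' Resting cascade state
#'
#' The no-stimulation equilibrium at resting calcium: all CaMKII in P0, and
#' (`ep`, `I1P`) at the fixed point of the PP1/inhibitor-1 subsystem,
#' `I1P* = v_PKA*I_0/(v_CaN*H3(c_rest))` and
#' `ep* = k4*e_p0/(k4 + k3*I1P*)`, where `H3` is the calcineurin calcium Hill
#' term. (At exactly zero calcium the I1P production term has no sink and no
#' equilibrium exists, so rest is defined at `c_rest`.)
#'
#' @param p A [cascade_params()] object.
#' @param c_rest Resting calcium (uM).
#' @return A [cascade_state()].
#' @export
cascade_rest_state <- function(p = cascade_params(), c_rest = 0.1) {
  stopifnot(c_rest > 0)
  h3 <- (c_rest / p$K_H2)^3
  H3 <- h3 / (1 + h3)
  I1P <- p$v_PKA * p$I_0 / (p$v_CaN * H3)
  ep <- p$k4 * p$e_p0 / (p$k4 + p$k3 * I1P)
  cascade_state(P = c(p$camkii_total, rep(0, 10)), ep = ep, I1P = I1P)
}

#' Cascade time derivatives
#'
#' The eleven-species phosphorylation ladder plus PP1 and inhibitor-1:
#' P0 -> P1 at rate v1 (uM/s), P_i -> P_(i+1) at `b_i*v2*P_i` with the ladder
#' coefficients (1, 1.8, 2.3, 2.7, 2.8, 2.7, 2.3, 1.8, 1), and
#' P_i -> P_(i-1) at `i*v3*P_i`. PP1 obeys mass action with I1P,
#' `dep/dt = -k3*I1P*ep + k4*(e_p0 - ep)`, and I1P adds PKA production and
#' calcium-dependent calcineurin removal. The ladder derivatives sum to zero
#' identically, so total CaMKII is conserved exactly even under forward
#' Euler.
#'
#' @param c_post Calcium concentration (uM).
#' @param state A [cascade_state()].
#' @param p A [cascade_params()] object.
#' @return List with `dP` (length 11), `dep`, `dI1P`, all per second.
#' @export
cascade_derivatives <- function(c_post, state, p = cascade_params()) {
  if (any(state$P < 0) || state$ep < 0 || state$ep > p$e_p0 || state$I1P < 0)
    stop("cascade state violates invariants: state-corruption error",
         call. = FALSE)
  rt <- cascade_rates(c_post, state, p)
  P <- state$P                      # P[1] = P0 ... P[11] = P10
  b <- ladder_coefficients()
  dP <- numeric(11)
  # forward flux f[i]: out of P[i] into P[i+1]; f0 is v1 (already has P0)
  fwd <- c(rt$v1, b * rt$v2 * P[2:10])      # length 10: P0->P1 ... P9->P10
  bwd <- (1:10) * rt$v3 * P[2:11]           # length 10: P1->P0 ... P10->P9
  dP[1] <- -fwd[1] + bwd[1]
  for (i in 2:10) dP[i] <- fwd[i - 1] - bwd[i - 1] - fwd[i] + bwd[i]
  dP[11] <- fwd[10] - bwd[10]
  mass <- -p$k3 * state$I1P * state$ep + p$k4 * (p$e_p0 - state$ep)
  h3 <- (c_post / p$K_H2)^3
  H3 <- h3 / (1 + h3)
  dI1P <- mass + p$v_PKA * p$I_0 - p$v_CaN * H3 * state$I1P
  list(dP = dP, dep = mass, dI1P = dI1P)
}

#' Phosphorylated CaMKII readout
#'
#' The total phosphorylated holoenzyme concentration, `sum(P1..P10)`
#' (P0 excluded); lies in `[0, camkii_total]`.
#'
#' @param state A [cascade_state()] (or any list with a `P` field of 11
#'   entries).
#' @return Phosphorylated CaMKII (uM).
#' @export
phosphorylated_camkii <- function(state) {
  sum(state$P[2:11])
}
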