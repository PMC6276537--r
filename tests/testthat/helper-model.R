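# Shared fixtures: small parameter sets and short-run configs used across
# the unit tests. Everything is generated in code; no stored data.

quick_config <- function(t_end = 0.5, seed = 1, dt = 0.05, stride = 20)
  sim_config(dt = dt, t_end = t_end, seed = seed, record_stride = stride)

# a cascade state with all eleven species occupied, for derivative checks
random_cascade_state <- function(p = cascade_params(), seed = 1) {
  set.seed(seed)
  w <- stats::runif(11)
  P <- p$camkii_total * w / sum(w)
  cascade_state(P, ep = stats::runif(1, 0, p$e_p0),
                I1P = stats::runif(1, 0, 10))
}

# deterministic sub-model right-hand side for deSolve (VGCC off), sharing the
# package's exported derivative functions; cascade rates are per second
deterministic_rhs <- function(params, protocol, condition) {
  stopifnot(!condition$vgcc)
  m <- params$membrane; a <- params$ampar; np <- params$nmdar
  cp <- params$calcium; cs <- params$cascade
  function(t, y, parms) {
    V <- y[1]; mA <- y[2]; mN <- y[3]; gVD <- y[4]; c_post <- max(y[5], 0)
    P <- y[6:16]; ep <- y[17]; I1P <- y[18]
    st <- cascade_state(pmax(P, 0), max(ep, 0), max(I1P, 0))
    Ph <- phosphorylated_camkii(st)
    gAMPA <- ampar_conductance_from_camkii(Ph, a)
    g_pre <- glutamate_at(protocol, t)
    Mg <- mg_block(V, condition$Op, np, condition$mg_effect, condition$form)
    gN <- nmdar_conductance(gVD, condition$Op, condition, np)
    I_A <- ampar_current(V, mA, gAMPA, a)
    I_N <- nmdar_current(V, mN, gN, Mg, np)
    dcas <- cascade_derivatives(c_post, st, cs)
    list(c(membrane_derivative(V, I_A, I_N, m),
           receptor_gating_derivative(mA, g_pre, a$alpha, a$beta),
           receptor_gating_derivative(mN, g_pre, np$alpha, np$beta),
           g_vd_derivative(gVD, V, np),
           calcium_derivative(c_post, I_A, I_N, 0, cp),
           1e-3 * dcas$dP, 1e-3 * dcas$dep, 1e-3 * dcas$dI1P))
  }
}

deterministic_init <- function(params) {
  cp <- params$calcium; cs <- params$cascade
  st <- cascade_rest_state(cs, cp$c_rest)
  c(params$membrane$V_rest, 0, 0, 0, cp$c_rest, st$P, st$ep, st$I1P)
}

# independent re-derivation of the pA -> uM/ms conversion used in tests
calcium_flux_per_pA_test <- function(p) {
  1e-12 / (p$Z_ca * 96487 * p$V_spine * 1e-15) * 1e6 * 1e-3
}
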