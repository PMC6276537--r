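# Assembly and integration of the full model.

# Fixed flattening order shared with src/engine.cpp; any change here must be
# mirrored there.
.flatten_params <- function(params, cond, protocol) {
  m <- params$membrane; a <- params$ampar; n <- params$nmdar
  v <- params$vgcc; ca <- params$calcium; cs <- params$cascade
  c(m$tau_post, m$V_rest, m$R_m,
    a$g_AMPA0, a$V_AMPA, a$alpha, a$beta, a$P_half, a$k_half,
    n$V_NMDA, n$alpha, n$beta, n$g_VI, n$tau_g, n$k_slope, n$V0,
    n$Mg_out, n$k0, n$z, n$delta, n$Temp,
    v$g_R, v$V_R, v$N, v$Vh_open, v$k_open,
    ca$eta, ca$gamma, ca$Z_ca, ca$V_spine, ca$b_t, ca$K_endo, ca$K_s,
    ca$c_rest,
    cs$e_p0, cs$I_0, cs$k3, cs$k4, cs$v_CaN, cs$v_PKA, cs$K_H2, cs$k1,
    cs$K_H1, cs$K_M, cs$k2, cs$camkii_total,
    cond$Op, as.numeric(cond$conductance_effect), as.numeric(cond$mg_effect),
    as.numeric(cond$vgcc), cond$nmdar_coeff, cond$vgcc_coeff,
    as.numeric(cond$form == "printed"),
    protocol$frequency, protocol$pulse_width, protocol$amplitude,
    protocol$duration)
}

.trace_names <- c("t", "g_pre", "V", "I_AMPA", "I_NMDA", "I_R", "c_post",
                  "Ph_CaMKII", "g_AMPA", "ep", "I1P", "m_AMPA", "m_NMDA",
                  "g_VD")

#' Simulate the spine model
#'
#' Integrates the assembled state (membrane potential, receptor gates,
#' voltage-dependent NMDAR conductance, spine calcium, the 11-species CaMKII
#' ladder, PP1 and inhibitor-1) with fixed-step forward Euler, one binomial
#' VGCC draw per step from R's seeded RNG stream, and a per-step refresh of
#' the AMPAR conductance from the phosphorylated-CaMKII readout.
#'
#' Initial state: `V = V_rest`, gates 0, `g_VD = 0`, `g_AMPA = g_AMPA0`,
#' `c = c_rest`, all CaMKII in P0, PP1/inhibitor-1 at their resting
#' equilibrium. Identical inputs and seed give bit-identical results.
#'
#' Per-step order: stimulus, Mg block and conductances, currents (including
#' the VGCC draw), membrane/calcium/cascade derivatives, Euler update, clamp
#' to invariant ranges, AMPAR-conductance refresh. Clamping events are
#' counted; a run in which more than 1e-4 of steps needed clamping aborts.
#'
#' @param params A [spine_params()] set.
#' @param protocol A [stimulus_protocol()].
#' @param condition An [opioid_condition()].
#' @param config A [sim_config()]; its `seed` (if non-NULL) is applied with
#'   `set.seed()` before integration.
#' @param engine `"cpp"` (compiled, default) or `"R"` (pure-R reference loop
#'   built from the exported derivative functions; slow, intended for
#'   cross-validation).
#' @param ltp_threshold Phosphorylated-CaMKII level (uM) above which the run
#'   is flagged as LTP; defaults to the AMPAR sigmoid midpoint.
#' @return An object of class `spine_sim`: list with `traces` (data frame of
#'   recorded time series), `summary` (peak/final phosphorylated CaMKII,
#'   final AMPAR conductance, LTP flag, clamping fraction), and the resolved
#'   inputs.
#' @examples
#' sim <- simulate_spine(config = sim_config(t_end = 0.5, seed = 1))
#' summary(sim)
#' @export
simulate_spine <- function(params = spine_params(),
                           protocol = stimulus_protocol(),
                           condition = opioid_condition(),
                           config = sim_config(),
                           engine = c("cpp", "R"),
                           ltp_threshold = params$ampar$P_half) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "spine_params"),
            inherits(protocol, "stimulus_protocol"),
            inherits(condition, "opioid_condition"),
            inherits(config, "sim_config"))
  n_steps <- round(config$t_end * 1000 / config$dt)
  if (!is.null(config$seed)) set.seed(config$seed)
  par <- .flatten_params(params, condition, protocol)
  out <- if (engine == "cpp") {
    .engine_cpp(par, config$dt, as.integer(n_steps), config$record_stride)
  } else {
    .engine_r(params, protocol, condition, config$dt, n_steps,
              config$record_stride)
  }
  traces <- as.data.frame(out$traces)
  names(traces) <- .trace_names
  breach_fraction <- out$breach_steps / n_steps
  if (breach_fraction > 1e-4)
    stop(sprintf(
      "state-corruption error: %.3g%% of steps required clamping",
      100 * breach_fraction), call. = FALSE)
  final_ph <- traces$Ph_CaMKII[nrow(traces)]
  summ <- list(
    peak_ph_camkii = out$peak_ph,
    final_ph_camkii = final_ph,
    final_g_ampa = traces$g_AMPA[nrow(traces)],
    ltp_induced = out$peak_ph > ltp_threshold,
    ltp_threshold = ltp_threshold,
    breach_fraction = breach_fraction)
  structure(list(traces = traces, summary = summ, final_state = out$final,
                 params = params, protocol = protocol, condition = condition,
                 config = config, engine = engine),
            class = "spine_sim")
}

# Pure-R reference integrator: same per-step order as the compiled engine,
# composed from the exported derivative functions. O(n_steps) R loop; use
# short horizons.
.engine_r <- function(params, protocol, condition, dt, n_steps, stride) {
  m <- params$membrane; a <- params$ampar; np <- params$nmdar
  vp <- params$vgcc; cp <- params$calcium; cs <- params$cascade
  st <- cascade_rest_state(cs, cp$c_rest)
  V <- m$V_rest; mA <- 0; mN <- 0; gVD <- 0; c_post <- cp$c_rest
  Ph <- 0
  gAMPA <- ampar_conductance_from_camkii(Ph, a)
  rows <- seq(0, n_steps, by = stride)
  if (rows[length(rows)] != n_steps) rows <- c(rows, n_steps)
  rec <- matrix(0, length(rows), 14)
  row <- 1
  peak_ph <- 0
  breach_steps <- 0
  Mg_fun <- function(V) mg_block(V, condition$Op, np, condition$mg_effect,
                                 condition$form)
  for (i in 0:n_steps) {
    t <- i * dt
    g_pre <- glutamate_at(protocol, t)
    Mg <- Mg_fun(V)
    gN <- nmdar_conductance(gVD, condition$Op, condition, np)
    I_A <- ampar_current(V, mA, gAMPA, a)
    I_N <- nmdar_current(V, mN, gN, Mg, np)
    I_R <- vgcc_current(V, condition, vp)
    if (i %in% rows) {
      rec[row, ] <- c(t, g_pre, V, I_A, I_N, I_R, c_post, Ph, gAMPA,
                      st$ep, st$I1P, mA, mN, gVD)
      row <- row + 1
    }
    if (i == n_steps) break
    dV <- membrane_derivative(V, I_A, I_N, m)
    dmA <- receptor_gating_derivative(mA, g_pre, a$alpha, a$beta)
    dmN <- receptor_gating_derivative(mN, g_pre, np$alpha, np$beta)
    dgVD <- g_vd_derivative(gVD, V, np)
    dc <- calcium_derivative(c_post, I_A, I_N, I_R, cp)
    dcas <- cascade_derivatives(c_post, st, cs)
    V <- V + dt * dV
    mA <- mA + dt * dmA
    mN <- mN + dt * dmN
    gVD <- gVD + dt * dgVD
    c_post <- c_post + dt * dc
    P <- st$P + dt * 1e-3 * dcas$dP
    ep <- st$ep + dt * 1e-3 * dcas$dep
    I1P <- st$I1P + dt * 1e-3 * dcas$dI1P
    breached <- mA < 0 || mA > 1 || mN < 0 || mN > 1 || gVD < 0 ||
      c_post < 0 || ep < 0 || ep > cs$e_p0 || I1P < 0 || any(P < 0)
    if (breached) breach_steps <- breach_steps + 1
    mA <- min(max(mA, 0), 1); mN <- min(max(mN, 0), 1)
    gVD <- max(gVD, 0); c_post <- max(c_post, 0)
    ep <- min(max(ep, 0), cs$e_p0); I1P <- max(I1P, 0)
    P <- pmax(P, 0)
    st <- cascade_state(P, ep, I1P)
    Ph <- phosphorylated_camkii(st)
    peak_ph <- max(peak_ph, Ph)
    gAMPA <- ampar_conductance_from_camkii(Ph, a)
  }
  list(traces = rec, peak_ph = peak_ph, breach_steps = breach_steps,
       final = list(V = V, m_AMPA = mA, m_NMDA = mN, g_VD = gVD,
                    c_post = c_post, g_AMPA = gAMPA, P = st$P, ep = st$ep,
                    I1P = st$I1P))
}

#' @export
print.spine_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Spine simulation: Op = %g uM, %g Hz / %g ms / %g mM, %g s\n",
              x$condition$Op, x$protocol$frequency, x$protocol$pulse_width,
              x$protocol$amplitude, x$config$t_end))
  cat(sprintf("  peak Ph.CaMKII : %8.3f uM\n", s$peak_ph_camkii))
  cat(sprintf("  final Ph.CaMKII: %8.3f uM\n", s$final_ph_camkii))
  cat(sprintf("  final g_AMPA   : %8.4f nS (baseline %g)\n",
              s$final_g_ampa, x$params$ampar$g_AMPA0))
  cat(sprintf("  LTP induced    : %s (threshold %g uM)\n",
              s$ltp_induced, s$ltp_threshold))
  invisible(x)
}

#' @export
summary.spine_sim <- function(object, ...) {
  s <- object$summary
  tr <- object$traces
  out <- c(peak_ph_camkii = s$peak_ph_camkii,
           final_ph_camkii = s$final_ph_camkii,
           final_g_ampa = s$final_g_ampa,
           peak_calcium = max(tr$c_post),
           peak_V = max(tr$V),
           ltp_induced = as.numeric(s$ltp_induced))
  class(out) <- c("summary.spine_sim", class(out))
  out
}

#' @export
print.summary.spine_sim <- function(x, ...) {
  print(unclass(round(x, 4)))
  invisible(x)
}

#' @export
as.data.frame.spine_sim <- function(x, ...) x$traces

#' Plot recorded traces of a simulation
#'
#' Stacked panels of the recorded quantities (stimulus, receptor and channel
#' currents, calcium, phosphorylated CaMKII with the LTP threshold, AMPAR
#' conductance), mirroring the standard presentation of this model.
#'
#' @param x A `spine_sim` object.
#' @param vars Trace columns to plot.
#' @param window Optional time window in seconds, e.g. `c(0, 1)`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spine_sim <- function(x, vars = c("g_pre", "I_AMPA", "I_NMDA", "I_R",
                                       "c_post", "Ph_CaMKII", "g_AMPA"),
                           window = NULL, ...) {
  tr <- x$traces
  if (!is.null(window))
    tr <- tr[tr$t >= window[1] * 1000 & tr$t <= window[2] * 1000, ]
  old <- graphics::par(mfrow = c(length(vars), 1),
                       mar = c(2, 4.2, 0.6, 0.6))
  on.exit(graphics::par(old))
  for (v in vars) {
    graphics::plot(tr$t / 1000, tr[[v]], type = "l", xlab = "",
                   ylab = v, ...)
    if (v == "Ph_CaMKII")
      graphics::abline(h = x$summary$ltp_threshold, col = "darkgreen",
                       lty = 2)
  }
  invisible(x)
}

#' LTP detection
#'
#' Flags LTP if the peak phosphorylated CaMKII strictly exceeds the
#' threshold (default: the AMPAR phosphorylation midpoint, 40 uM).
#'
#' @param result A `spine_sim` object.
#' @param threshold Threshold (uM).
#' @return Logical flag.
#' @export
ltp_detect <- function(result, threshold = result$params$ampar$P_half) {
  stopifnot(inherits(result, "spine_sim"))
  result$summary$peak_ph_camkii > threshold
}

#' Step-size self-convergence check
#'
#' Re-runs the deterministic sub-model (VGCC disabled) at each step size in
#' `dt_list` and reports the maximum absolute deviation of the membrane
#' potential and calcium traces from the run with the smallest step size,
#' compared on the common time grid.
#'
#' @param params,protocol,condition,config Simulation inputs; the condition's
#'   VGCC toggle is forced off.
#' @param dt_list Step sizes to compare (ms). Must share a common recorded
#'   grid (each dt must divide `record_ms`).
#' @param record_ms Comparison grid spacing (ms).
#' @return Data frame with one row per dt: `dt`, `max_dV`, `max_dc`.
#' @export
convergence_check <- function(params = spine_params(),
                              protocol = stimulus_protocol(),
                              condition = opioid_condition(Op = 1),
                              config = sim_config(t_end = 1),
                              dt_list = c(0.025, 0.05, 0.1),
                              record_ms = 1) {
  condition$vgcc <- FALSE
  dt_list <- sort(dt_list)
  runs <- lapply(dt_list, function(dt) {
    stride <- round(record_ms / dt)
    stopifnot(abs(stride * dt - record_ms) < 1e-9)
    cfg <- sim_config(dt = dt, t_end = config$t_end,
                      record_stride = stride)
    simulate_spine(params, protocol, condition, cfg)$traces
  })
  ref <- runs[[1]]
  n <- min(vapply(runs, nrow, 1L))
  res <- data.frame(
    dt = dt_list,
    max_dV = vapply(runs, function(tr)
      max(abs(tr$V[1:n] - ref$V[1:n])), 1.0),
    max_dc = vapply(runs, function(tr)
      max(abs(tr$c_post[1:n] - ref$c_post[1:n])), 1.0))
  res
}
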