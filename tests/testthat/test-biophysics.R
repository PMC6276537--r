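test_that("opioid saturation is zero without opioid, monotone, saturating", {
  expect_equal(opioid_saturation(0), 0)
  ops <- c(0, 0.01, 0.1, 1, 10, 1000)
  s <- opioid_saturation(ops)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s < 1))
  expect_equal(opioid_saturation(1e9), 1, tolerance = 1e-6)
  # printed (literal) form decreases from 1 instead
  sp <- opioid_saturation(ops, form = "printed")
  expect_equal(sp[1], 1)
  expect_true(all(diff(sp) < 0))
})

test_that("Mg block has hyperpolarized limit 0, depolarized limit 1", {
  p <- nmdar_params()
  for (op in c(0, 1, 50)) {
    expect_lt(mg_block(-1000, op, p), 1e-6)
    expect_gt(mg_block(1000, op, p), 1 - 1e-6)
  }
})

test_that("Mg block matches hand-evaluated closed forms at V = 0", {
  p <- nmdar_params()
  # exponential term is 1 at V = 0, so the factor reduces to an affinity ratio
  expect_equal(mg_block(0, 0, p, form = "printed"),
               1 / (1 + p$Mg_out / (p$k0 + 15.58)))
  expect_equal(mg_block(0, 0, p, form = "saturating"),
               1 / (1 + p$Mg_out / p$k0))
})

test_that("Mg block is strictly increasing in V for any fixed opioid level", {
  p <- nmdar_params()
  V <- seq(-100, 100, by = 1)
  for (op in c(0, 0.5, 1, 10)) {
    expect_true(all(diff(mg_block(V, op, p)) > 0))
  }
})

test_that("opioid relieves the Mg block and mg_effect freezes it", {
  p <- nmdar_params()
  V <- seq(-80, -20, by = 5)
  expect_true(all(mg_block(V, 1, p) > mg_block(V, 0, p)))
  expect_identical(mg_block(V, 1, p, mg_effect = FALSE), mg_block(V, 0, p))
})

test_that("NMDAR conductance combines baseline, opioid term and g_VD", {
  p <- nmdar_params()
  expect_equal(nmdar_conductance(0, 0, opioid_condition(0), p), p$g_VI)
  # conductance knockout reproduces the opioid-free value at any dose
  ck0 <- opioid_condition(5, conductance_effect = FALSE)
  expect_equal(nmdar_conductance(0.2, 5, ck0, p),
               nmdar_conductance(0.2, 0, opioid_condition(0), p))
  # saturation limit of the opioid term is 0.15 nS at coefficient 1
  expect_equal(nmdar_conductance(0, 1e9, opioid_condition(1e9), p),
               p$g_VI + 0.15, tolerance = 1e-6)
  # non-decreasing in Op
  g <- vapply(c(0, 0.1, 1, 10), function(op)
    nmdar_conductance(0, op, opioid_condition(op), p), 1.0)
  expect_true(all(diff(g) > 0))
})

test_that("g_VD relaxes to a floored linear target", {
  p <- nmdar_params()
  expect_equal(g_vd_derivative(0, p$V0, p), 0)
  expect_equal(g_vd_derivative(0, p$V0 - 20, p), 0)  # floor active
  # closed-form exponential relaxation at constant V above V0: after one
  # time constant g reaches (1 - exp(-1)) of its target
  V <- p$V0 + 10
  g_inf <- p$k_slope * 10
  g <- 0; dt <- 0.01
  for (i in seq_len(round(p$tau_g / dt)))
    g <- g + dt * g_vd_derivative(g, V, p)
  expect_equal(g, g_inf * (1 - exp(-1)), tolerance = 1e-3)
})

test_that("receptor gating has the analytic fixed point and stays in [0,1]", {
  expect_equal(receptor_gating_derivative(0, 0, 1.1, 0.19), 0)
  # steady state under constant glutamate
  a <- 1.1; b <- 0.19; g <- 0.3
  m_inf <- a * g / (a * g + b)
  expect_equal(receptor_gating_derivative(m_inf, g, a, b), 0)
  # random bounded pulse trains never push the gate outside [0,1]
  set.seed(42)
  for (rep in 1:5) {
    m <- runif(1)
    g_seq <- sample(c(0, runif(1, 0, 2)), 2000, replace = TRUE)
    for (g_pre in g_seq)
      m <- m + 0.05 * receptor_gating_derivative(m, g_pre, a, b)
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("gating trajectory under a pulse train matches a stiff-solver oracle", {
  skip_if_not_installed("deSolve")
  stim <- stimulus_protocol()
  a <- nmdar_params()$alpha; b <- nmdar_params()$beta
  # package path: forward Euler at 0.05 ms
  dt <- 0.05
  t_end <- 1000
  m <- 0
  m_euler <- numeric(t_end + 1)
  for (i in 0:(t_end / dt)) {
    if (i %% (1 / dt) == 0) m_euler[i * dt + 1] <- m
    m <- m + dt * receptor_gating_derivative(m, glutamate_at(stim, i * dt),
                                             a, b)
  }
  # oracle: lsoda integrated piecewise over constant-glutamate segments
  edges <- sort(unique(c(seq(0, t_end, by = 200),
                         seq(4, t_end, by = 200), t_end)))
  m_ref <- 0
  ref <- numeric(t_end + 1); ref[1] <- 0
  for (k in seq_len(length(edges) - 1)) {
    tt <- seq(edges[k], edges[k + 1], by = 1)
    g_seg <- glutamate_at(stim, edges[k])
    sol <- deSolve::lsoda(c(m = m_ref), tt,
                          function(t, y, pr) list(a * g_seg * (1 - y) -
                                                    b * y),
                          NULL, rtol = 1e-10, atol = 1e-12)
    ref[tt + 1] <- sol[, "m"]
    m_ref <- unname(sol[nrow(sol), "m"])
  }
  expect_lt(max(abs(m_euler - ref)) / max(ref), 0.005)
})

test_that("AMPAR current obeys the ohmic product form", {
  p <- ampar_params()
  expect_equal(ampar_current(-70, 0, 0.4, p), 0)
  expect_equal(ampar_current(p$V_AMPA, 0.7, 0.4, p), 0)
  expect_equal(ampar_current(p$V_AMPA - 70, 0.5, 0.4, p), -14)
})

test_that("NMDAR current is the product of independently computed factors", {
  p <- nmdar_params()
  expect_equal(nmdar_current(-60, 0.3, 0.5, 0, p), 0)
  expect_equal(nmdar_current(p$V_NMDA, 0.3, 0.5, 0.2, p), 0)
  V <- -48; m <- 0.21; gvd <- 0.07; op <- 0.8
  cond <- opioid_condition(op)
  got <- nmdar_current(V, m, nmdar_conductance(gvd, op, cond, p),
                       mg_block(V, op, p), p)
  manual <- (p$g_VI + 0.15 * opioid_saturation(op) + gvd) * m *
    mg_block(V, op, p) * (V - p$V_NMDA)
  expect_equal(got, manual)
})

test_that("AMPAR conductance sigmoid has endpoints 0.4, 0.6 and 0.8 nS", {
  p <- ampar_params()
  expect_equal(ampar_conductance_from_camkii(0, p), 0.4, tolerance = 1e-12)
  expect_equal(ampar_conductance_from_camkii(p$P_half, p), 0.6)
  expect_equal(ampar_conductance_from_camkii(1e6, p), 0.8)
  ph <- seq(0, 100, by = 0.5)
  g <- ampar_conductance_from_camkii(ph, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g > 0.4 - 1e-12 & g < 0.8 + 1e-12))
  # strictly increasing where the sigmoid has not underflowed
  near <- seq(30, 50, by = 0.5)
  expect_true(all(diff(ampar_conductance_from_camkii(near, p)) > 0))
})

test_that("VGCC current vanishes when toggled off or at the reversal", {
  p <- vgcc_params()
  set.seed(1)
  expect_identical(vgcc_current(0, opioid_condition(1, vgcc = FALSE), p), 0)
  expect_equal(vgcc_current(p$V_R, opioid_condition(1), p), 0)
})

test_that("Monte-Carlo VGCC mean matches the analytic binomial mean", {
  p <- vgcc_params()
  cond <- opioid_condition(1)
  V <- p$Vh_open + 2   # well-activated so the draw is informative
  set.seed(7)
  draws <- replicate(1e5, vgcc_current(V, cond, p))
  popen <- vgcc_open_probability(V, p)
  per_channel <- p$g_R * 1e-3 * (V - p$V_R)
  mu <- p$N * popen * per_channel
  se <- sqrt(p$N * popen * (1 - popen)) * abs(per_channel) / sqrt(1e5)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("pump rate is linear and symmetric around resting calcium", {
  p <- calcium_params()
  expect_equal(pump_rate(0.1, p), 0)
  expect_equal(pump_rate(1.1, p), 0.1)      # 100 uM/s = 0.1 uM/ms
  expect_equal(pump_rate(0.05, p), -0.005)  # -5 uM/s below rest
})

test_that("calcium derivative has a resting fixed point and correct fluxes", {
  p <- calcium_params()
  expect_equal(calcium_derivative(p$c_rest, 0, 0, 0, p), 0)
  expect_lt(calcium_derivative(1, 0, 0, 0, p), 0)  # pump-driven decay
  # hand-evaluated flux for a -10 pA NMDAR current at rest:
  # gamma * 10 pA / (Z * F * V_spine) scaled by the rapid-buffer factor
  raw <- 0.06 * 10 * 1e-12 / (2 * 96487 * 0.9048e-15) * 1e6 * 1e-3
  theta <- 200 * 10 / (10 + 0.1)^2
  expect_equal(calcium_derivative(0.1, 0, -10, 0, p), raw / (1 + theta))
  expect_error(calcium_derivative(-0.1, 0, 0, 0, p), "state-corruption")
})

test_that("membrane relaxes to rest and follows the closed-form response", {
  p <- membrane_params()
  expect_equal(membrane_derivative(p$V_rest, 0, 0, p), 0)
  # constant synaptic current: V(t) = V_rest + R*I*1e-3*(1 - exp(-t/tau))
  I_syn <- 5  # pA, via I_AMPA = -5
  V <- p$V_rest; dt <- 0.001
  for (i in 1:(3 * p$tau_post / dt)) V <- V + dt *
      membrane_derivative(V, -I_syn, 0, p)
  expect_equal(V, p$V_rest + p$R_m * I_syn * 1e-3 * (1 - exp(-3)),
               tolerance = 1e-4)
})
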