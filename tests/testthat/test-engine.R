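test_that("identical seeds give bit-identical trajectories", {
  a <- simulate_spine(condition = opioid_condition(1),
                      config = quick_config(t_end = 1, seed = 7))
  b <- simulate_spine(condition = opioid_condition(1),
                      config = quick_config(t_end = 1, seed = 7))
  expect_identical(a$traces, b$traces)
  expect_identical(a$summary, b$summary)
})

test_that("zero-amplitude stimulus leaves the deterministic model at rest", {
  params <- spine_params()
  stim <- stimulus_protocol(amplitude = 0)
  sim <- simulate_spine(params, stim, opioid_condition(0, vgcc = FALSE),
                        quick_config(t_end = 10, stride = 200))
  tr <- sim$traces
  expect_lt(max(abs(tr$V - params$membrane$V_rest)), 1e-6 * 70)
  expect_lt(max(abs(tr$c_post - params$calcium$c_rest)), 1e-6)
  expect_equal(max(tr$g_VD), 0)
  expect_equal(max(tr$m_AMPA), 0)
  expect_equal(max(tr$Ph_CaMKII), 0, tolerance = 1e-9)
  expect_equal(max(tr$g_AMPA), params$ampar$g_AMPA0, tolerance = 1e-12)
})

test_that("resting VGCC pool is effectively silent", {
  # sparse single-channel blips at rest perturb calcium negligibly: the
  # mean open-channel count at the resting potential corresponds to a
  # steady calcium elevation far below resting calcium itself
  p <- vgcc_params()
  cp <- calcium_params()
  mean_I <- p$N * vgcc_open_probability(-70, p) * p$g_R * 1e-3 *
    abs(-70 - p$V_R)
  elevation <- mean_I * calcium_flux_per_pA_test(cp) / (cp$K_s * 1e-3)
  expect_lt(elevation, 0.01)
})

test_that("gates stay in [0,1] and concentrations non-negative under drive", {
  for (seed in 1:3) {
    set.seed(seed)
    stim <- stimulus_protocol(frequency = runif(1, 1, 20),
                              pulse_width = runif(1, 1, 40),
                              amplitude = runif(1, 0, 1))
    sim <- simulate_spine(protocol = stim,
                          condition = opioid_condition(runif(1, 0, 2)),
                          config = quick_config(t_end = 2, seed = seed))
    tr <- sim$traces
    expect_true(all(tr$m_AMPA >= 0 & tr$m_AMPA <= 1))
    expect_true(all(tr$m_NMDA >= 0 & tr$m_NMDA <= 1))
    expect_true(all(tr$c_post >= 0))
    expect_true(all(tr$g_VD >= 0))
    expect_equal(sim$summary$breach_fraction, 0)
  }
})

test_that("CaMKII mass is conserved exactly along full simulations", {
  for (op in c(0, 1)) {
    sim <- simulate_spine(condition = opioid_condition(op),
                          config = quick_config(t_end = 2, seed = 1))
    total <- sum(sim$final_state$P)
    expect_equal(total, cascade_params()$camkii_total, tolerance = 1e-12)
    expect_true(all(sim$traces$ep >= 0 &
                      sim$traces$ep <= cascade_params()$e_p0))
    expect_true(all(sim$traces$I1P >= 0))
  }
})

test_that("compiled engine and pure-R reference engine agree", {
  cfg <- quick_config(t_end = 0.2, seed = 3, stride = 10)
  for (cond in list(opioid_condition(0, vgcc = FALSE),
                    opioid_condition(1, vgcc = FALSE))) {
    a <- simulate_spine(condition = cond, config = cfg, engine = "cpp")
    b <- simulate_spine(condition = cond, config = cfg, engine = "R")
    expect_equal(a$traces$V, b$traces$V, tolerance = 1e-10)
    expect_equal(a$traces$c_post, b$traces$c_post, tolerance = 1e-10)
    expect_equal(a$traces$Ph_CaMKII, b$traces$Ph_CaMKII, tolerance = 1e-10)
  }
})

test_that("deterministic sub-model matches an adaptive-integrator oracle", {
  skip_if_not_installed("deSolve")
  params <- spine_params()
  protocol <- stimulus_protocol()
  condition <- opioid_condition(1, vgcc = FALSE)
  t_end <- 2000  # ms
  sim <- simulate_spine(params, protocol, condition,
                        sim_config(t_end = t_end / 1000, seed = 1,
                                   record_stride = 20))
  rhs <- deterministic_rhs(params, protocol, condition)
  y0 <- deterministic_init(params)
  # integrate segment-wise between pulse edges so lsoda never steps across
  # a stimulus discontinuity
  period <- 1000 / protocol$frequency
  edges <- sort(unique(c(seq(0, t_end, by = period),
                         seq(protocol$pulse_width, t_end, by = period),
                         t_end)))
  out <- matrix(NA_real_, nrow = t_end + 1, ncol = length(y0))
  out[1, ] <- y0
  y <- y0
  for (k in seq_len(length(edges) - 1)) {
    tt <- unique(c(edges[k], seq(ceiling(edges[k]), edges[k + 1], by = 1),
                   edges[k + 1]))
    sol <- deSolve::lsoda(y, tt, rhs, NULL, rtol = 1e-8, atol = 1e-10)
    keep <- tt == floor(tt)
    out[tt[keep] + 1, ] <- sol[keep, -1]
    y <- sol[nrow(sol), -1]
  }
  grid <- sim$traces$t <= t_end
  V_euler <- sim$traces$V[grid]
  c_euler <- sim$traces$c_post[grid]
  V_ref <- out[, 1]; c_ref <- out[, 5]
  expect_lt(max(abs(V_euler - V_ref)) / diff(range(V_ref)), 0.01)
  expect_lt(max(abs(c_euler - c_ref)) / max(c_ref), 0.01)
})

test_that("self-convergence improves as dt shrinks and flags coarse steps", {
  res <- convergence_check(config = sim_config(t_end = 0.5),
                           dt_list = c(0.025, 0.05, 0.2, 1))
  expect_equal(res$max_dV[1], 0)
  expect_equal(res$max_dc[1], 0)
  # deviations grow with dt
  expect_true(all(diff(res$max_dV) >= 0))
  expect_lt(res$max_dV[2], 0.5)   # production step close to refined run
  expect_gt(res$max_dV[4] + res$max_dc[4], res$max_dV[2] + res$max_dc[2])
})

test_that("LTP detector uses a strict threshold on peak phosphorylation", {
  sim <- simulate_spine(condition = opioid_condition(0),
                        config = quick_config(t_end = 0.2))
  expect_false(ltp_detect(sim))
  fake <- sim
  fake$summary$peak_ph_camkii <- 40
  expect_false(ltp_detect(fake, threshold = 40))  # boundary is exclusive
  fake$summary$peak_ph_camkii <- 40.0001
  expect_true(ltp_detect(fake, threshold = 40))
})

test_that("trace recording is consistent with the requested stride", {
  cfg <- sim_config(dt = 0.05, t_end = 0.1, seed = 1, record_stride = 40)
  sim <- simulate_spine(config = cfg)
  expect_equal(sim$traces$t[1:3], c(0, 2, 4))
  expect_equal(tail(sim$traces$t, 1), 100)
  # summary scalars recomputable from traces
  expect_equal(sim$summary$final_g_ampa, tail(sim$traces$g_AMPA, 1))
})
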