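test_that("first synaptic event starts from fully recovered resources", {
  st <- evolve_states(default_params(), stimulus_train(0))
  expect_equal(st$u_post[1], 0.3)
  expect_equal(st$A_post[1], 0.3)
  expect_equal(st$R_post[1], 0.7)
  # full utilization consumes everything at once
  st1 <- evolve_states(synapse_params(1, 8, 400, 60, 1), stimulus_train(0))
  expect_equal(st1$A_post[1], 1)
  expect_equal(st1$R_post[1], 0)
})

test_that("analytic event states match the four-state ODE oracle", {
  p <- synapse_params(1, 5, 500, 50, 0.5)
  tr <- stimulus_train(c(0, 20))
  st <- evolve_states(p, tr)
  orc <- four_state_oracle(p, tr, dt = 1e-3, t_end = 20.001)
  rows <- which(orc$time_ms == 20)
  expect_equal(orc$A[rows[1]], st$A_pre[2], tolerance = 1e-6)
  expect_equal(orc$A[rows[2]], st$A_post[2], tolerance = 1e-6)
  expect_equal(orc$u[rows[2]], st$u_post[2], tolerance = 1e-6)
  expect_equal(orc$R[rows[2]], st$R_post[2], tolerance = 1e-6)
})

test_that("resources are conserved in both formalisms", {
  set.seed(11)
  p <- random_params()
  tr <- regular_train(6, 15)
  st <- evolve_states(p, tr)
  expect_true(all(abs(st$A_pre + st$R_pre + st$D_pre - 1) < 1e-9))
  expect_true(all(abs(st$A_post + st$R_post + st$D_post - 1) < 1e-9))
  orc <- four_state_oracle(p, tr, dt = 0.5)
  expect_true(all(abs(orc$A + orc$R + orc$D - 1) < 1e-9))
  # rest: before the first event everything stays recovered
  orc0 <- four_state_oracle(p, stimulus_train(60), dt = 0.5)
  early <- orc0[orc0$time_ms < 60, ]
  expect_true(all(early$A == 0 & early$D == 0 & early$R == 1))
})

test_that("the tau_d == tau_r degeneracy uses the analytic limit", {
  p_deg <- synapse_params(1, 100, 100 + 1e-9, 50, 0.4)
  p_near <- synapse_params(1, 100, 100.001, 50, 0.4)
  tr <- regular_train(4, 30)
  st_deg <- evolve_states(p_deg, tr)
  st_near <- evolve_states(p_near, tr)
  expect_equal(st_deg$A_post, st_near$A_post, tolerance = 1e-5)
  expect_true(all(is.finite(st_deg$R_pre)))
  orc <- four_state_oracle(p_deg, tr, dt = 1e-2)
  rows <- which(orc$time_ms == 90)
  expect_equal(orc$R[rows[1]], st_deg$R_pre[4], tolerance = 1e-6)
})

test_that("simulated conductance has peak g and pure exponential decay", {
  p <- default_params()
  sig <- simulate_conductance(p, stimulus_train(0))
  expect_equal(max(sig$value), p$g)
  # between events the decay is exponential with constant tau_d
  sel <- sig$time_ms >= 1 & sig$time_ms <= 30
  lr <- diff(log(sig$value[sel])) / diff(sig$time_ms[sel])
  expect_equal(lr, rep(-1 / p$tau_d, length(lr)), tolerance = 1e-9)
  # linearity in g
  p2 <- synapse_params(2, 8, 400, 60, 0.3)
  sig2 <- simulate_conductance(p2, stimulus_train(0))
  expect_equal(sig2$value, 2 * sig$value, tolerance = 1e-12)
  expect_warning(simulate_conductance(p, stimulus_train(0), dt = 2),
                 "undersampled")
})

test_that("voltage-clamp current follows Ohm's law in the driving force", {
  p <- default_params()
  sig <- simulate_conductance(p, stimulus_train(0))
  czero <- simulate_current(sig, recording_conditions(E_rev = -70, V_h = -70))
  expect_true(all(czero$value == 0))
  cur <- simulate_current(sig, vc_conditions())
  expect_equal(max(cur$value), 35)  # 1 nS * (-35 - (-70)) mV
  cur2 <- simulate_current(sig, recording_conditions(E_rev = -70, V_h = 0))
  expect_equal(cur2$value, cur$value * 2, tolerance = 1e-12)
  expect_error(simulate_current(cur, vc_conditions()), "conductance")
})

test_that("RC membrane integration matches the closed form", {
  mem <- membrane_model(V_ss = -65, C_m = 100, tau_m = 20)
  grid <- seq(0, 100, by = 0.05)
  quiet <- synaptr:::.new_signal(grid, rep(0, length(grid)), "current", "pA")
  v0 <- simulate_voltage(quiet, mem)
  expect_true(all(abs(v0$value - -65) < 1e-8))
  inj <- synaptr:::.new_signal(grid, rep(50, length(grid)), "current", "pA")
  v <- simulate_voltage(inj, mem)
  closed <- -65 + (50 / mem$g_in) * (1 - exp(-v$time_ms / 20))
  expect_equal(v$value, closed, tolerance = 1e-4)
  # halving C_m at fixed g_in halves tau_m and the 63% rise time
  mem2 <- membrane_model(V_ss = -65, C_m = 50, g_in = mem$g_in)
  expect_equal(mem2$tau_m, 10)
  v2 <- simulate_voltage(inj, mem2)
  rise63 <- function(vv) {
    target <- -65 + 0.63 * (50 / mem$g_in)
    vv$time_ms[which(vv$value >= target)[1]]
  }
  expect_equal(rise63(v2) / rise63(v), 0.5, tolerance = 0.02)
  expect_error(simulate_voltage(synaptr:::.new_signal(c(0, 50), c(0, 0),
                                                      "current", "pA"), mem),
               "grid step")
})

test_that("facilitation and depression limits behave as expected", {
  # tau_f -> 0 with ISI >> tau_f: utilization resets to U at every event
  p <- synapse_params(1, 8, 400, 1e-3, 0.3)
  st <- evolve_states(p, regular_train(6, 50))
  expect_equal(st$u_post, rep(0.3, 6), tolerance = 1e-9)
  # ISI >> tau_r and tau_d as well: every amplitude equals U
  p2 <- synapse_params(1, 5, 80, 1e-3, 0.25)
  st2 <- evolve_states(p2, regular_train(5, 2000))
  expect_equal(st2$A_post - st2$A_pre, rep(0.25, 5), tolerance = 1e-6)
})

test_that("periodic stimulation drives amplitudes to a fixed point", {
  p <- synapse_params(1, 8, 300, 80, 0.4)
  st <- evolve_states(p, regular_train(30, 20))
  amp <- st$A_post - st$A_pre
  d <- abs(diff(amp))
  expect_true(all(diff(d[10:29]) <= 1e-12))
  expect_lt(d[28], 1e-6)
})

test_that("synaptometrics reproduces the model's ratio definitions", {
  p <- synapse_params(1, 5, 500, 50, 0.5)
  tr <- stimulus_train(c(0, 20))
  sig <- simulate_conductance(p, tr)
  sm <- synaptometrics(sig)
  st <- evolve_states(p, tr)
  # PPR_{i:1} = (u+ R-)_i / (u+ R-)_1
  ppr_states <- (st$u_post * st$R_pre) / (st$u_post[1] * st$R_pre[1])
  expect_equal(sm$events$ppr_i1, ppr_states, tolerance = 1e-9)
  # AB_i : A_1 = A_{ti+} / A_{t1+}
  expect_equal(sm$events$ab_i_a1, st$A_post / st$A_post[1], tolerance = 1e-9)
  # single event: self-ratio is 1 and the half-height width is tau_d ln 2
  sm1 <- synaptometrics(simulate_conductance(p, stimulus_train(0), dt = 0.01))
  expect_equal(sm1$events$ab_i_a1[1], 1)
  expect_equal(sm1$kinetics$value_ms[sm1$kinetics$metric == "half_height_width"],
               p$tau_d * log(2), tolerance = 1e-3)
  # rise times are undefined for instantaneous-rise simulated traces
  expect_true(is.na(sm1$kinetics$value_ms[sm1$kinetics$metric == "rise_10_90"]))
})

test_that("input validation catches malformed parameters and trains", {
  expect_error(synapse_params(-1, 8, 400, 60, 0.3), "positive")
  expect_error(synapse_params(1, 8, 400, 60, 1.5), "U")
  expect_error(stimulus_train(c(0, 0, 10)), "increasing")
  expect_error(stimulus_train(c(0, 10), recovery_index = 1), "last event")
  expect_error(four_state_oracle(default_params(), stimulus_train(0), dt = 50),
               "too large")
  expect_error(membrane_model(V_ss = -65, C_m = 100, tau_m = 20, g_in = 20),
               "inconsistent")
})
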