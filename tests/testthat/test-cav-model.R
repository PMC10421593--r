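test_that("steady-state activation follows the Boltzmann sigmoid", {
  p <- default_params()
  # half-maximal at V_Cav50 by definition
  expect_equal(steady_open_probability(-17, p), 0.5)
  # direct evaluation 20 mV below half-activation
  expect_equal(steady_open_probability(-37, p), 1 / (1 + exp(4)),
               tolerance = 1e-12)
  # sigmoid limits
  expect_equal(steady_open_probability(1e4, p), 1)
  expect_lt(steady_open_probability(-1e4, p), 1e-300 + 1e-10)
  expect_equal(steady_sensor_activation(1e4, p), 1)
  # strictly increasing in V
  v <- seq(-120, 100, by = 1)
  expect_true(all(diff(steady_open_probability(v, p)) > 0))
  # algebraic identity: sensor activation is the fourth root
  expect_equal(steady_sensor_activation(v, p)^4,
               steady_open_probability(v, p), tolerance = 1e-12)
  expect_equal(steady_sensor_activation(-17, p), 0.5^0.25)
  expect_error(steady_open_probability(NaN, p),
               class = "cavprime_invalid_input")
})

test_that("sensor velocity switches between activation and deactivation branches", {
  p <- default_params()
  # activation branch: v = k_on * P_steady
  expect_equal(sensor_velocity(0.07, 0.992, p), 0.55 * 0.992)
  # deactivation branch: v = k_off * (1 - P_steady)
  expect_equal(sensor_velocity(0.9, 0.1, p), 0.65 * 0.9)
  # tie: drive term zero, so the step leaves P unchanged regardless of branch
  pss <- steady_sensor_activation(-30, p)
  expect_identical(step_sensor(pss, -30, p), pss)
  expect_error(sensor_velocity(-0.1, 0.5, p),
               class = "cavprime_invalid_input")
  expect_error(sensor_velocity(0.5, 1.2, p),
               class = "cavprime_invalid_input")
})

test_that("one Euler step matches the hand-evaluated update and is bounded", {
  p <- default_params()
  pss <- steady_sensor_activation(0, p)
  expect_equal(step_sensor(0, 0, p), 0.01 * (0.55 * pss) * pss,
               tolerance = 1e-12)
  # step size bound |dP| <= dt * max(k_on, k_off)
  set.seed(11)
  for (i in 1:50) {
    p0 <- runif(1)
    v0 <- runif(1, -120, 80)
    expect_lte(abs(step_sensor(p0, v0, p) - p0),
               p$dt * max(p$k_on, p$k_off) + 1e-12)
  }
})

test_that("state occupancies are the binomial masses over four sensors", {
  expect_equal(unname(state_occupancies(0)), c(1, 0, 0, 0, 0))
  # independent oracle: binomial pmf with n = 4
  for (pa in c(0.05, 0.25, 0.5, 0.77, 0.97)) {
    expect_equal(unname(state_occupancies(pa)), dbinom(0:4, 4, pa),
                 tolerance = 1e-12)
  }
  # normalization for arbitrary activation values
  pa <- seq(0, 1, by = 0.01)
  expect_true(all(abs(rowSums(state_occupancies(pa)) - 1) < 1e-12))
  expect_error(state_occupancies(1.01), class = "cavprime_invalid_input")
})

test_that("simulated current respects the driving force and steady state", {
  p <- default_params()
  # command clamped at E_Ca gives exactly zero current
  stim <- voltage_trace(rep(p$E_Ca, 500), p$dt)
  expect_true(all(simulate_current(stim, p)$current$I == 0))
  # long hold converges to the steady I-V point
  for (v in c(-40, 0, 30)) {
    hold <- voltage_trace(rep(v, round(120 / p$dt)), p$dt)
    sim <- simulate_current(hold, p, P_init = 0.2)
    expect_lt(abs(tail(sim$current$I, 1) -
                    steady_open_probability(v, p) * (v - p$E_Ca)), 1e-6)
  }
  # steady initialization is a fixed point of the integrator
  hold <- voltage_trace(rep(-55, 2000), p$dt)
  sim <- simulate_current(hold, p, P_init = "steady")
  expect_lt(max(abs(sim$P_act - sim$P_act[1])), p$dt * 1e-12)
  expect_error(simulate_current(voltage_trace(rep(0, 10), 0.02), p),
               class = "cavprime_config_error")
})

test_that("occupancy conservation holds at every simulated sample", {
  p <- default_params()
  stim <- build_epsp_ap_waveform(epsp_ap_spec(), p)
  sim <- simulate_current(stim, p)
  expect_lt(max(abs(rowSums(sim$occupancy) - 1)), 1e-10)
})

test_that("steady I-V curve has its inward peak between V_Cav50 and E_Ca", {
  p <- default_params()
  iv <- steady_iv_curve(seq(-80, 60, by = 0.25), p)
  expect_equal(iv$I[iv$V == p$E_Ca], 0)
  # direct evaluation at half-activation
  expect_equal(iv$I[iv$V == -17], 0.5 * (-17 - 60))
  vmin <- iv$V[which.min(iv$I)]
  expect_gt(vmin, p$V_Cav50)
  expect_lt(vmin, p$E_Ca)
  expect_error(steady_iv_curve(numeric(0), p),
               class = "cavprime_invalid_input")
})

test_that("augmentation ratio is 1 for identical traces and errors on zero control", {
  p <- default_params()
  stim <- step_protocol(p, dur = 5, post = 5)
  sim <- simulate_current(stim, p)
  w <- attr(stim, "step_window")
  expect_equal(augmentation_ratio(sim$current, sim$current, w), 1)
  flat <- current_trace(rep(0, length(stim$V)), p$dt)
  expect_error(augmentation_ratio(sim$current, flat, w),
               class = "cavprime_undefined_ratio")
})

test_that("Euler trajectories converge as the step is refined", {
  p <- default_params()
  stim <- step_protocol(p)
  cc <- euler_convergence(stim, p, refine = 10)
  expect_lt(cc$rel_error, 0.01)
  # a coarser step is less accurate than the default
  p2 <- cav_params(dt = 0.02)
  cc2 <- euler_convergence(step_protocol(p2), p2, refine = 20)
  expect_gt(cc2$rel_error, cc$rel_error)
})

test_that("parameter validation enforces the model invariants", {
  expect_error(cav_params(alpha = 0), class = "cavprime_invalid_input")
  expect_error(cav_params(dt = 0.1), class = "cavprime_invalid_input")
  expect_error(cav_params(E_Ca = -30), class = "cavprime_invalid_input")
  expect_s3_class(cav_params(), "cav_params")
})
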