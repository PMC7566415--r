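# Integration, trace structure, and output conventions.

test_that("experiment configuration rejects non-physical settings", {
  expect_error(experiment_config(duration = 0), "positive")
  expect_error(experiment_config(output_step = -1), "positive")
  expect_error(experiment_config(rtol = 0), "positive")
  expect_error(experiment_config(solver = "euler"))
})

test_that("traces sit on the uniform output grid with both conventions", {
  cfg <- experiment_config(duration = 10, output_step = 0.05)
  tr <- simulate_hh(build_hh_model(hh_parameters(v_init = -15)), cfg)
  expect_equal(nrow(tr), 10 / 0.05 + 1)
  expect_equal(tr$time_ms, seq(0, 10, by = 0.05))
  expect_equal(tr$Vm_mV, -75 - tr$V_mV) # Vm = E_r - V elementwise
  expect_named(tr, c("time_ms", "V_mV", "Vm_mV", "n", "m", "h",
                     "iNa_uAcm2", "iK_uAcm2", "iL_uAcm2"))
})

test_that("measured-potential conversion is its own inverse", {
  expect_equal(to_measured_potential(0, -75), -75)
  expect_equal(to_measured_potential(-100, -75), 25)
  v <- seq(-120, 40, by = 7.3)
  expect_equal(to_measured_potential(to_measured_potential(v, -75), -75), v)
})

test_that("config overrides reach the model parameters", {
  m <- build_hh_model(hh_parameters(v_init = -15, i_const = 0))
  tr <- simulate_hh(m, experiment_config(duration = 5, v_init = 0,
                                         i_const = 0))
  expect_lt(max(abs(tr$Vm_mV + 75)), 1e-6)
  # a steady hyperpolarizing (positive outward) current raises V
  tr2 <- simulate_hh(m, experiment_config(duration = 20, v_init = 0,
                                          i_const = 2))
  expect_gt(tr2$V_mV[nrow(tr2)], 1)
})

test_that("trace comparison reports max and rms differences", {
  cfg <- experiment_config(duration = 5)
  a <- simulate_hh(build_hh_model(hh_parameters(v_init = -15)), cfg)
  expect_equal(as.numeric(compare_traces(a, a)), c(0, 0))
  b <- a
  b$Vm_mV <- b$Vm_mV + 1
  expect_equal(as.numeric(compare_traces(a, b)), c(1, 1))
  short <- simulate_hh(build_hh_model(hh_parameters(v_init = -15)),
                       experiment_config(duration = 2))
  expect_error(compare_traces(a, short), "grids")
})

test_that("repeated runs are bitwise identical", {
  cfg <- experiment_config(duration = 10, solver = "rk4")
  m <- build_hh_model(hh_parameters(v_init = -15))
  expect_identical(as.data.frame(simulate_hh(m, cfg)),
                   as.data.frame(simulate_hh(m, cfg)))
  cfg2 <- experiment_config(duration = 10)
  expect_identical(as.data.frame(simulate_hh(m, cfg2)),
                   as.data.frame(simulate_hh(m, cfg2)))
})

test_that("rk4 and lsoda agree on the action potential upstroke", {
  m <- build_hh_model(hh_parameters(v_init = -15))
  a <- simulate_hh(m, experiment_config(duration = 10, solver = "lsoda"))
  b <- simulate_hh(m, experiment_config(duration = 10, solver = "rk4"))
  expect_lt(max(abs(a$Vm_mV - b$Vm_mV)), 0.01)
})

test_that("the solution is converged at the default tolerances", {
  m <- build_hh_model(hh_parameters(v_init = -15))
  coarse <- simulate_hh(m, experiment_config(duration = 20))
  fine <- simulate_hh(m, experiment_config(duration = 20,
                                           output_step = 0.0125,
                                           rtol = 1e-9, atol = 1e-11))
  # compare on the shared (coarse) grid so only the solver error remains
  shared <- fine[seq(1, nrow(fine), by = 2), ]
  expect_lt(max(abs(coarse$Vm_mV - shared$Vm_mV)), 0.01)
  expect_lt(abs(max(coarse$Vm_mV) - max(shared$Vm_mV)), 0.01)
})

test_that("warming the membrane shortens the time to peak", {
  m <- build_hh_model(hh_parameters(v_init = -15))
  cold <- simulate_hh(m, experiment_config(duration = 20, temperature = 6.3))
  warm <- simulate_hh(m, experiment_config(duration = 20, temperature = 16.3))
  t_cold <- cold$time_ms[which.max(cold$Vm_mV)]
  t_warm <- warm$time_ms[which.max(warm$Vm_mV)]
  expect_lt(t_warm, t_cold)
})

test_that("summaries and plots derive from the trace", {
  tr <- simulate_hh(build_hh_model(hh_parameters(v_init = -15)),
                    experiment_config(duration = 20))
  g <- glance(tr)
  expect_equal(g$duration_ms, 20)
  expect_gt(g$peak_Vm_mV, 0)
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})
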