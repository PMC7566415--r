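# Rate fitting functions and gate kinetics primitives.

test_that("exponential and logistic fits evaluate their closed forms", {
  expect_equal(exp_fit(0, sx = 5, sy = 0.7), 0.7)
  expect_equal(exp_fit(1, 1, 1), exp(1))
  expect_equal(exp_fit(0, sx = 1 / 80, sy = 0.125), 0.125) # beta_n at rest
  expect_equal(logistic_fit(-30, x0 = -30, sx = 0.1, sy = 1), 0.5)
  expect_equal(logistic_fit(7, x0 = 7, sx = 3, sy = 4), 2) # midpoint
  expect_equal(logistic_fit(0, x0 = -30, sx = 0.1, sy = 1),
               0.04742587, tolerance = 1e-6) # beta_h at rest
  # flat logistic limit: sx = 0 gives sy/2 everywhere
  expect_equal(logistic_fit(c(-50, 0, 50), x0 = 3, sx = 0, sy = 2),
               c(1, 1, 1))
})

test_that("goldman fit matches the classic rates and is continuous at x0", {
  expect_equal(goldman_fit(0, x0 = -10, sx = 0.1, sy = 0.01),
               0.05819767, tolerance = 1e-6) # alpha_n at rest
  expect_equal(goldman_fit(0, x0 = -25, sx = 0.1, sy = 0.1),
               0.22356372, tolerance = 1e-6) # alpha_m at rest
  # removable singularity: value is the analytic limit sy / sx
  expect_identical(goldman_fit(-10, x0 = -10, sx = 0.1, sy = 0.01), 0.01 / 0.1)
  # continuity: the deviation from the limit shrinks linearly (slope sy/2)
  for (e in 10^-(3:12)) {
    expect_lt(abs(goldman_fit(-10 + e, -10, 0.1, 0.01) - 0.1), 0.006 * e + 1e-15)
    expect_lt(abs(goldman_fit(-10 - e, -10, 0.1, 0.01) - 0.1), 0.006 * e + 1e-15)
  }
  expect_true(all(is.finite(goldman_fit(seq(-200, 100, by = 0.5),
                                        x0 = -10, sx = 0.1, sy = 0.01))))
})

test_that("gate steady state follows the rate balance and rejects dead rates", {
  same <- fit_exponential(sx = 0.02, sy = 3)
  expect_equal(gate_steady_state(same, same, -40), 0.5)
  r <- hh_rate_functions()
  expect_equal(gate_steady_state(r$alpha_n, r$beta_n, 0),
               0.3176769, tolerance = 1e-6)
  expect_equal(gate_steady_state(r$alpha_h, r$beta_h, 0),
               0.5961208, tolerance = 1e-6)
  dead <- fit_exponential(sx = 0, sy = 0)
  expect_error(gate_steady_state(dead, dead, 0), "degenerate")
})

test_that("gate derivative vanishes at steady state and is linear at bounds", {
  r <- hh_rate_functions()
  for (v in c(-80, -30, 0, 20)) {
    n_inf <- gate_steady_state(r$alpha_m, r$beta_m, v)
    expect_equal(gate_derivative(n_inf, v, 2.7, r$alpha_m, r$beta_m), 0,
                 tolerance = 1e-15)
    expect_equal(gate_derivative(0, v, 1.5, r$alpha_m, r$beta_m),
                 1.5 * r$alpha_m(v))
    expect_equal(gate_derivative(1, v, 1.5, r$alpha_m, r$beta_m),
                 -1.5 * r$beta_m(v))
  }
})

test_that("temperature factor is an exact power law in 10-degree steps", {
  expect_equal(temperature_factor(6.3, 6.3, 3), 1)
  expect_equal(temperature_factor(16.3, 6.3, 3), 3)
  expect_equal(temperature_factor(26.3, 6.3, 3), 9)
  expect_equal(temperature_factor(1.3, 6.3, 2), 2^-0.5)
  expect_error(temperature_factor(10, 6.3, q10 = 0), "positive")
})

test_that("conductance laws implement the molecular stoichiometry", {
  expect_equal(potassium_conductance(1, 36), 36)
  expect_equal(potassium_conductance(0.5, 36), 36 / 16)
  expect_equal(potassium_conductance(0, 36), 0)
  expect_equal(sodium_conductance(1, 1, 120), 120)
  expect_equal(sodium_conductance(0.5, 1, 120), 120 / 8)
  expect_equal(sodium_conductance(0.9, 0, 120), 0) # full inactivation
})

test_that("tau/inf form is the exact algebraic twin of the rate form", {
  set.seed(42)
  for (rep in 1:20) {
    fo <- fit_exponential(sx = stats::runif(1, -0.1, 0.1), sy = stats::runif(1, 0.01, 2))
    fc <- fit_logistic(x0 = stats::runif(1, -60, 0), sx = stats::runif(1, 0, 0.2),
                       sy = stats::runif(1, 0.01, 2))
    n_inf <- function(v) gate_steady_state(fo, fc, v)
    tau <- function(v) 1 / (fo(v) + fc(v))
    v <- stats::runif(1, -100, 30)
    n <- stats::runif(1)
    expect_equal(tau_inf_gate_derivative(n, v, n_inf, tau),
                 gate_derivative(n, v, 1, fo, fc), tolerance = 1e-12)
  }
  expect_equal(tau_inf_gate_derivative(0, 0, function(v) 1, function(v) 2), 0.5)
  expect_error(
    tau_inf_gate_derivative(0.5, 0, function(v) 1, function(v) -1),
    "positive"
  )
})
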