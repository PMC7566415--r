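# The concrete membrane components and their extensions.

test_that("default parameters balance the resting state exactly", {
  p <- hh_parameters()
  expect_equal(p$e_l, -10.5989209694, tolerance = 1e-9)
  y0 <- monolithic_initial_state(p, v_init = 0)
  cur <- hhsim:::monolithic_currents(as.list(y0), p)
  expect_lt(abs(cur$i_na + cur$i_k + cur$i_l), 1e-12)
  expect_error(hh_parameters(c = 0), "positive")
  expect_error(hh_parameters(g_na = -1), "positive")
})

test_that("gate initialization tracks the fitting parameters automatically", {
  set.seed(3)
  for (rep in 1:10) {
    fo <- fit_goldman(x0 = stats::runif(1, -40, -5), sx = stats::runif(1, 0.05, 0.2),
                      sy = stats::runif(1, 0.005, 0.1))
    fc <- fit_exponential(sx = stats::runif(1, 0.005, 0.05),
                          sy = stats::runif(1, 0.05, 4))
    g <- gate(fo, fc)
    sys <- flatten(
      circuit_model(cap = lipid_bilayer(v_init = 0), k = potassium_channel(),
                    gnd = ground_component()) |>
        connect_electrical("cap.p", "k.p") |>
        connect_electrical("cap.p", "gnd.p") |>
        connect_electrical("cap.n", "k.n") |>
        connect_signal("cap.temp", "k.temp")
    )
    # the shipped potassium gate initializes at its own steady state
    expect_equal(sys$initial_state[["k.gate_act.n"]],
                 gate_steady_state(hh_rate_functions()$alpha_n,
                                   hh_rate_functions()$beta_n, 0))
    # and a randomized gate initializes at the steady state of ITS rates
    eq <- g$equations[[1]]
    expect_equal(eq$init_fn(g), gate_steady_state(fo, fc, 0))
  }
})

test_that("a lone gate stays within [0, 1] under bounded voltage drive", {
  set.seed(19)
  for (rep in 1:8) {
    fo <- fit_exponential(sx = stats::runif(1, -0.1, 0.1),
                          sy = stats::runif(1, 0.01, 3))
    fc <- fit_logistic(x0 = stats::runif(1, -60, 0),
                       sx = stats::runif(1, -0.2, 0.2),
                       sy = stats::runif(1, 0.01, 3))
    n0 <- stats::runif(1)
    v_of_t <- function(t) 40 * sin(t / 2) - 30 # bounded drive
    sol <- deSolve::ode(
      y = c(n = n0), times = seq(0, 30, by = 0.1),
      func = function(t, y, p) list(gate_derivative(y, v_of_t(t), 1, fo, fc)),
      parms = NULL
    )
    expect_true(all(sol[, "n"] >= -1e-9 & sol[, "n"] <= 1 + 1e-9))
  }
})

test_that("the model holds rest and fires on a suprathreshold stimulus", {
  rest <- simulate_hh(build_hh_model(hh_parameters(v_init = 0, i_const = 0)))
  expect_lt(max(abs(rest$Vm_mV + 75)), 1e-6)

  ap <- simulate_hh(build_hh_model(hh_parameters(v_init = -15)))
  expect_gt(max(ap$Vm_mV), 0)
  expect_lt(abs(ap$Vm_mV[nrow(ap)] + 75), 1)
  expect_true(all(ap$n >= 0 & ap$n <= 1))
  expect_true(all(ap$m >= 0 & ap$m <= 1))
  expect_true(all(ap$h >= 0 & ap$h <= 1))
})

test_that("removing the leak channel forfeits the stable resting state", {
  p <- hh_parameters(v_init = 0, i_const = 0)
  m <- circuit_model(
    bilayer = lipid_bilayer(c = p$c, v_init = 0, temp_m = p$temperature),
    potassium = potassium_channel(),
    sodium = sodium_channel(),
    clamp = current_clamp(0)
  ) |>
    connect_electrical("bilayer.p", "potassium.p") |>
    connect_electrical("potassium.p", "sodium.p") |>
    connect_electrical("sodium.p", "clamp.p") |>
    connect_electrical("bilayer.n", "potassium.n") |>
    connect_electrical("potassium.n", "sodium.n") |>
    connect_electrical("sodium.n", "clamp.n") |>
    connect_signal("bilayer.temp", "potassium.temp") |>
    connect_signal("bilayer.temp", "sodium.temp")
  expect_no_issues(m)
  tr <- simulate_hh(flatten(m), experiment_config(duration = 50))
  expect_gt(max(abs(tr$bilayer.v)), 1e-3) # drifts away from rest
})

test_that("slow inactivation with p_slow = 0 reproduces the base channel", {
  expect_error(sodium_channel_slow_inactivation(p_slow = 1.2), "0, 1")
  base <- sodium_channel()
  slow0 <- sodium_channel_slow_inactivation(p_slow = 0)
  eq_of <- function(comp, name) {
    Filter(function(e) e$name == name, comp$equations)[[1]]
  }
  g_base <- eq_of(base, "open_channel_conductance")
  g_slow <- eq_of(slow0, "open_channel_conductance")
  pars_base <- lapply(base$parameters, `[[`, "value")
  pars_slow <- lapply(slow0$parameters, `[[`, "value")
  set.seed(5)
  for (rep in 1:50) {
    m <- stats::runif(1); h <- stats::runif(1); hs <- stats::runif(1)
    v <- stats::runif(1, -110, 30)
    gb <- g_base$fn(list(gate_act.n = m, gate_inact.n = h), pars_base, NULL)
    gs <- g_slow$fn(list(gate_act.n = m, gate_inact.n = h, gate_slow.n = hs),
                    pars_slow, NULL)
    expect_equal(gs, gb, tolerance = 1e-12)
    # identical gate dynamics => identical branch current i = g (v - v_eq)
    expect_equal(gs * (v - pars_slow$v_eq), gb * (v - pars_base$v_eq),
                 tolerance = 1e-12)
  }
  # p_slow = 1 with h_slow following the fast dynamics is the base channel too
  r <- hh_rate_functions()
  slow1 <- sodium_channel_slow_inactivation(p_slow = 1,
                                            slow_fopen = r$alpha_h,
                                            slow_fclose = r$beta_h)
  g_slow1 <- eq_of(slow1, "open_channel_conductance")
  pars_slow1 <- lapply(slow1$parameters, `[[`, "value")
  expect_equal(
    g_slow1$fn(list(gate_act.n = 0.4, gate_inact.n = 0.9, gate_slow.n = 0.7),
               pars_slow1, NULL),
    g_base$fn(list(gate_act.n = 0.4, gate_inact.n = 0.7), pars_base, NULL),
    tolerance = 1e-15
  )
  # stated convex combination: m = 1, h_fast = 1, h_slow = 0, p_slow = 0.5
  half <- sodium_channel_slow_inactivation(p_slow = 0.5)
  g_half <- eq_of(half, "open_channel_conductance")
  pars_half <- lapply(half$parameters, `[[`, "value")
  expect_equal(
    g_half$fn(list(gate_act.n = 1, gate_inact.n = 1, gate_slow.n = 0),
              pars_half, NULL),
    pars_half$g_max / 2
  )
})

test_that("the slow-inactivation channel simulates inside the full model", {
  p <- hh_parameters(v_init = -15)
  m <- circuit_model(
    bilayer = lipid_bilayer(c = p$c, v_init = p$v_init, temp_m = p$temperature),
    potassium = potassium_channel(),
    sodium = sodium_channel_slow_inactivation(p_slow = 0),
    leak = leak_channel(),
    clamp = current_clamp(0)
  ) |>
    connect_electrical("bilayer.p", "potassium.p") |>
    connect_electrical("potassium.p", "sodium.p") |>
    connect_electrical("sodium.p", "leak.p") |>
    connect_electrical("leak.p", "clamp.p") |>
    connect_electrical("bilayer.n", "potassium.n") |>
    connect_electrical("potassium.n", "sodium.n") |>
    connect_electrical("sodium.n", "leak.n") |>
    connect_electrical("leak.n", "clamp.n") |>
    connect_signal("bilayer.temp", "potassium.temp") |>
    connect_signal("bilayer.temp", "sodium.temp")
  expect_no_issues(m)
  sys <- flatten(m)
  expect_equal(nrow(sys$state_layout), 5) # extra slow gate state
  tr <- simulate_hh(sys, experiment_config(duration = 20))
  ref <- simulate_hh(build_hh_model(p), experiment_config(duration = 20))
  # p_slow = 0: voltage trajectory identical to the standard model
  expect_lt(max(abs(tr$bilayer.v - ref$V_mV)), 1e-6)
})

test_that("the tau/inf gate with the identity mapping matches the rate gate", {
  r <- hh_rate_functions()
  n_inf <- function(v) gate_steady_state(r$alpha_n, r$beta_n, v)
  tau <- function(v) 1 / (r$alpha_n(v) + r$beta_n(v))
  g_ab <- gate(r$alpha_n, r$beta_n)
  g_ti <- gate_tau_inf(n_inf, tau)
  eq_ab <- g_ab$equations[[1]]
  eq_ti <- g_ti$equations[[1]]
  expect_equal(eq_ti$init_fn(g_ti), eq_ab$init_fn(g_ab), tolerance = 1e-15)
  set.seed(8)
  for (rep in 1:30) {
    d <- list(n = stats::runif(1), v = stats::runif(1, -110, 30),
              temp = stats::runif(1, 0, 30))
    expect_equal(eq_ti$fn(d, NULL, g_ti$functions),
                 eq_ab$fn(d, NULL, g_ab$functions), tolerance = 1e-12)
  }
})
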