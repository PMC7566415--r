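# Shared fixtures, all built in code.

# capacitor driven by a constant current, closed form v(t) = v0 + (i/c) * t
toy_ramp_circuit <- function(c = 1, i_const = 1, v0 = 0) {
  circuit_model(
    cap = lipid_bilayer(c = c, v_init = v0),
    src = constant_current(i_const),
    gnd = ground_component()
  ) |>
    connect_electrical("cap.p", "gnd.p") |>
    connect_electrical("cap.p", "src.n") |>
    connect_electrical("cap.n", "src.p")
}

# capacitor in parallel with an ohmic leak, closed form
# v(t) = v_eq + (v0 - v_eq) * exp(-(g/c) * t)
toy_rc_circuit <- function(c = 1, g = 0.5, v_eq = -3, v0 = 10) {
  circuit_model(
    cap = lipid_bilayer(c = c, v_init = v0),
    leak = leak_channel(g_max = g, v_eq = v_eq),
    gnd = ground_component()
  ) |>
    connect_electrical("cap.p", "gnd.p") |>
    connect_electrical("cap.p", "leak.p") |>
    connect_electrical("cap.n", "leak.n")
}

# random state in the physiological range, for rhs cross-checks
random_hh_state <- function() {
  c(V = stats::runif(1, -110, 30),
    n = stats::runif(1), m = stats::runif(1), h = stats::runif(1))
}

# maximum over nodes of |sum of member pin currents| at one state
max_node_current_residual <- function(sys, y, t = 0) {
  obs <- sys$observables(t, y)
  nodes <- sys$nodes
  residual <- vapply(split(nodes$pin, nodes$node), function(pins) {
    sum(obs[paste0(pins, ".i")])
  }, numeric(1))
  max(abs(residual))
}

expect_no_issues <- function(model) {
  expect_identical(validate_circuit(model), character(0))
}
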