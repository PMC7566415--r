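# Connection semantics, node partition, and model validation.

test_that("electrical connections reject unknown pins and signal ports", {
  m <- circuit_model(cap = lipid_bilayer(), gnd = ground_component())
  expect_error(connect_electrical(m, "cap.p", "cap.q"), "unknown pin")
  expect_error(connect_electrical(m, "nosuch.p", "gnd.p"), "unknown pin")
  expect_error(connect_electrical(m, "cap.temp", "gnd.p"), "signal port")
})

test_that("signal connections enforce direction and single drivers", {
  m <- circuit_model(cap = lipid_bilayer(), na = sodium_channel(),
                     k = potassium_channel())
  expect_error(connect_signal(m, "na.temp", "k.temp"), "output port")
  expect_error(connect_signal(m, "cap.temp", "cap.temp"), "input port")
  m <- connect_signal(m, "cap.temp", "na.temp")
  # fan-out of one output to a second input is fine
  m <- connect_signal(m, "cap.temp", "k.temp")
  expect_length(m$signals, 2)
  expect_error(connect_signal(m, "cap.temp", "na.temp"), "driver")
})

test_that("node partition is the transitive closure of the connections", {
  m <- circuit_model(a = constant_current(1), b = constant_current(1))
  # no connections: 4 singleton nodes
  expect_equal(dplyr::n_distinct(partition_nodes(m)$node), 4)
  # self-connection keeps the model valid and the pin in one node
  m1 <- connect_electrical(m, "a.p", "a.p")
  expect_equal(dplyr::n_distinct(partition_nodes(m1)$node), 4)
  # chain a-b, c-d, b-c merges all four pins into one node
  m2 <- m |>
    connect_electrical("a.p", "a.n") |>
    connect_electrical("b.p", "b.n") |>
    connect_electrical("a.n", "b.p")
  nodes <- partition_nodes(m2)
  expect_equal(dplyr::n_distinct(nodes$node), 1)
  expect_equal(nrow(nodes), 4)
})

test_that("the full membrane model partitions into two membrane nodes", {
  nodes <- partition_nodes(build_hh_model())
  counts <- dplyr::count(nodes, node, is_ground)
  expect_equal(nrow(counts), 2)
  # extracellular node: 5 positive pins plus ground and source pins
  expect_equal(sort(counts$n), c(6, 7))
  expect_equal(sum(counts$is_ground), 1)
  # all pins in a node share its potential by construction
  sys <- flatten(build_hh_model())
  obs <- sys$observables(0, sys$initial_state)
  for (k in unique(nodes$node)) {
    pots <- obs[paste0(nodes$pin[nodes$node == k], ".v")]
    expect_true(all(pots == pots[1]))
  }
})

test_that("count_connects tallies model-level electrical and signal links", {
  expect_equal(count_connects(circuit_model()), 0)
  m <- circuit_model(a = constant_current(), b = constant_current()) |>
    connect_electrical("a.p", "b.p")
  expect_equal(count_connects(m), 1)
  expect_equal(count_connects(build_hh_model()), 10)
})

test_that("validation reports missing ground, unbound inputs, partials", {
  expect_no_issues(build_hh_model())

  # remove the temperature connection to the sodium channel
  m <- build_hh_model()
  m$signals <- m$signals[1]
  issues <- validate_circuit(m)
  expect_match(issues, "unbound temperature input", all = FALSE)

  # no ground reference anywhere
  m2 <- circuit_model(cap = lipid_bilayer(), leak = leak_channel()) |>
    connect_electrical("cap.p", "leak.p") |>
    connect_electrical("cap.n", "leak.n")
  expect_match(validate_circuit(m2), "no ground", all = FALSE)

  # a partial component cannot be instantiated directly
  m3 <- circuit_model(chan = ion_channel(), gnd = ground_component())
  expect_match(validate_circuit(m3), "partial", all = FALSE)
})

test_that("flatten refuses invalid models and cyclic algebra", {
  m <- circuit_model(cap = lipid_bilayer(), leak = leak_channel()) |>
    connect_electrical("cap.p", "leak.p") |>
    connect_electrical("cap.n", "leak.n")
  expect_error(flatten(m), "not valid")

  looped <- component("Looped") |>
    add_variable("a") |>
    add_variable("b") |>
    add_equation("a_from_b", "algebraic", target = "a", depends = "b",
                 fn = function(d, p, f) d$b + 1) |>
    add_equation("b_from_a", "algebraic", target = "b", depends = "a",
                 fn = function(d, p, f) d$a + 1)
  m2 <- circuit_model(x = looped, gnd = ground_component())
  expect_error(flatten(m2), "loop")
})
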