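# Cognitive-load accounting under the fixed counting convention.

test_that("the gate presents five variables and one equation", {
  g <- gate(fit_exponential(1, 1), fit_exponential(1, 1))
  cnt <- item_count(g)
  expect_equal(cnt$n_variables, 5) # n, v, temp, fopen, fclose
  expect_equal(cnt$n_parameters, 0)
  expect_equal(cnt$n_equations, 1)
  # the two sodium-channel gates together are twelve items
  expect_equal(2 * cnt$n_items, 12)
})

test_that("local counting attributes inherited items to the base class", {
  tp <- item_count(lipid_bilayer(), class = "TwoPinComponent")
  expect_equal(tp$n_variables, 4) # p, n, v, i
  expect_equal(tp$n_equations, 1) # the current balance; two aliases uncounted
  bl <- item_count(lipid_bilayer())
  expect_equal(bl$n_parameters, 3) # c, v_init, temp_m
  expect_equal(bl$n_variables, 1) # temp output port
  expect_equal(bl$n_equations, 1) # capacitor law; temp forwarding is an alias
  ic <- item_count(potassium_channel(), class = "IonChannel")
  expect_equal(ic$n_variables, 1) # g
  expect_equal(ic$n_parameters, 2) # g_max, v_eq
  expect_equal(ic$n_equations, 1) # i = g (v - v_eq)
  k <- item_count(potassium_channel())
  expect_equal(k$n_variables, 1) # the gate instance
  expect_equal(k$n_equations, 1) # conductance law
  expect_equal(k$n_connects, 2) # v and temp routed to the gate
  # an empty component counts nothing
  empty <- item_count(component("Empty"))
  expect_equal(unlist(empty[-1]), c(n_variables = 0, n_parameters = 0,
                                    n_equations = 0, n_connects = 0,
                                    n_items = 0))
})

test_that("counting is structural: values never change the counts", {
  a <- item_count(potassium_channel())
  b <- item_count(potassium_channel(g_max = 99, v_eq = -1))
  expect_identical(a, b)
  # composing components into a model leaves individual counts unchanged
  prof <- model_load_profile(build_hh_model(hh_parameters(g_k = 99)))
  row <- dplyr::filter(prof$per_component, component == "PotassiumChannel")
  expect_equal(row$n_items, a$n_items)
})

test_that("the model profile reproduces the per-component maxima", {
  prof <- model_load_profile(build_hh_model())
  per <- prof$per_component
  expect_true(all(per$n_equations <= 2))
  expect_true(all(per$n_variables + per$n_parameters <= 5))
  top <- dplyr::filter(per, component == "HHmodular")
  expect_equal(top$n_variables, 5)
  expect_equal(top$n_connects, 10)
  expect_equal(prof$max_simultaneous, 6) # the Gate: 5 variables + 1 equation
  expect_lte(prof$max_simultaneous, prof$total)
  expect_lte(max(per$n_equations), monolithic_count()$n_equations)
  # a model of one empty component has nothing to hold in memory
  empty_prof <- model_load_profile(circuit_model(x = component("Empty")))
  expect_equal(max(empty_prof$per_component$n_equations), 0)
})

test_that("the monolithic declaration tallies 15 equations, 33 items", {
  mono <- monolithic_count()
  expect_equal(mono$n_equations, 15)
  expect_equal(mono$n_variables + mono$n_parameters, 33)
  # dropping one declared equation lowers the count by exactly one
  enum <- monolithic_enumeration()
  reduced <- monolithic_count(enumeration = enum[enum$name != "leak_current", ])
  expect_equal(reduced$n_equations, mono$n_equations - 1)
})

test_that("the reduction factor divides the monolithic total by the modular peak", {
  prof <- model_load_profile(build_hh_model())
  mono <- monolithic_count()
  expect_equal(reduction_factor(mono, prof), 48 / prof$max_simultaneous)
  expect_gte(reduction_factor(mono, prof), 6)
  # degenerate profile: equal totals give factor 1
  fake <- prof
  fake$max_simultaneous <- mono$n_items
  expect_equal(reduction_factor(mono, fake), 1)
  fake$max_simultaneous <- 1
  expect_equal(reduction_factor(mono, fake), mono$n_items)
  fake$max_simultaneous <- 0
  expect_error(reduction_factor(mono, fake), "degenerate")
})

test_that("tidy and glance expose the profile as tibbles", {
  prof <- model_load_profile(build_hh_model())
  expect_s3_class(tidy(prof), "tbl_df")
  g <- glance(prof)
  expect_equal(g$max_simultaneous, prof$max_simultaneous)
  sys <- flatten(build_hh_model())
  expect_equal(nrow(tidy(sys)), 4)
  expect_equal(glance(sys)$n_states, 4)
})
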