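# Cognitive-load accounting. The counting convention, fixed here and used
# everywhere:
#   * only locally declared items count (inherited items count in the base
#     class, matching a reader who walks the hierarchy base-first);
#   * each pin and each port counts as one variable (one carried quantity
#     slot exposed to the reader);
#   * each replaceable rate-function slot counts as one variable;
#   * each sub-component instance counts as one variable;
#   * alias definitions (pure renamings such as v = p.v - n.v) are not
#     counted as equations; initialization rules are not counted;
#   * internal connections and bindings count as connect equations, not as
#     ordinary equations.

count_items_for_origin <- function(comp, origin) {
  n_var <- sum(vapply(comp$variables, function(x) identical(x$origin, origin), logical(1))) +
    sum(vapply(comp$pins, function(x) identical(x$origin, origin), logical(1))) +
    sum(vapply(comp$ports, function(x) identical(x$origin, origin), logical(1))) +
    sum(vapply(comp$functions, function(x) identical(attr(x, "origin"), origin), logical(1))) +
    sum(vapply(comp$subcomponents, function(x) identical(x$declared_origin, origin), logical(1)))
  n_par <- sum(vapply(comp$parameters, function(x) identical(x$origin, origin), logical(1)))
  n_eq <- sum(vapply(comp$equations, function(e) {
    identical(e$origin, origin) && e$kind != "alias"
  }, logical(1)))
  n_con <- sum(vapply(comp$connections, function(x) identical(x$origin, origin), logical(1))) +
    sum(vapply(comp$bindings, function(x) identical(x$origin, origin), logical(1)))
  c(n_variables = n_var, n_parameters = n_par, n_equations = n_eq,
    n_connects = n_con)
}

#' Count the working-memory items of a component
#'
#' Tallies the locally declared variables, parameters, equations and
#' connect equations of one component class under the fixed counting
#' convention (see Details in the package vignette): pins, ports,
#' replaceable rate functions and sub-component instances each count as one
#' variable; alias definitions and initialization rules are not counted as
#' equations.
#'
#' @param comp An `hh_component`.
#' @param class Which class of the component's inheritance chain to count;
#'   defaults to the most derived class.
#' @return A one-row tibble: `component`, `n_variables`, `n_parameters`,
#'   `n_equations`, `n_connects`, `n_items` (their sum excluding connects).
#' @export
#' @examples
#' item_count(gate(fit_exponential(1, 1), fit_exponential(1, 1)))
item_count <- function(comp, class = comp$class) {
  stopifnot(inherits(comp, "hh_component"))
  if (!class %in% comp$class_chain) {
    stop(sprintf("'%s' is not in the class chain of '%s'", class, comp$class),
         call. = FALSE)
  }
  cnt <- count_items_for_origin(comp, class)
  tibble::tibble(
    component = class,
    n_variables = unname(cnt["n_variables"]),
    n_parameters = unname(cnt["n_parameters"]),
    n_equations = unname(cnt["n_equations"]),
    n_connects = unname(cnt["n_connects"]),
    n_items = unname(cnt["n_variables"] + cnt["n_parameters"] + cnt["n_equations"])
  )
}

#' Per-component cognitive-load profile of a model
#'
#' Walks every component class a reader of the model encounters (including
#' the partial base classes and the top-level composition) and counts its
#' locally declared items. `max_simultaneous` is the maximum of
#' variables + parameters + equations over the non-partial classes: the
#' largest number of interacting items a reader must hold in working memory
#' at once when moving through the model component by component.
#'
#' @param model An `hh_circuit`.
#' @param top_name Label for the top-level composition row.
#' @return An object of class `hh_load_profile`: a list with
#'   `per_component` (tibble), `max_simultaneous`, and `total` (sum of all
#'   items over all classes).
#' @export
#' @examples
#' profile <- model_load_profile(build_hh_model())
#' profile$max_simultaneous
model_load_profile <- function(model, top_name = "HHmodular") {
  stopifnot(inherits(model, "hh_circuit"))
  instances <- walk_instances(model)
  rows <- list()
  seen <- character()
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (cls in rev(comp$class_chain)) { # base classes first
      if (cls %in% seen) next
      seen <- c(seen, cls)
      row <- item_count(comp, cls)
      row$partial <- cls %in% c(comp$partial_classes,
                                if (comp$partial) comp$class)
      rows[[length(rows) + 1L]] <- row
    }
  }
  top <- tibble::tibble(
    component = top_name,
    n_variables = length(model$components),
    n_parameters = 0L,
    n_equations = 0L,
    n_connects = count_connects(model),
    n_items = length(model$components),
    partial = FALSE
  )
  per <- dplyr::bind_rows(c(rows, list(top)))
  per <- dplyr::relocate(per, "partial", .after = "component")
  max_sim <- if (any(!per$partial)) max(per$n_items[!per$partial]) else 0L
  structure(
    list(per_component = per, max_simultaneous = max_sim,
         total = sum(per$n_items)),
    class = "hh_load_profile"
  )
}

#' @export
print.hh_load_profile <- function(x, ...) {
  cat("<hh_load_profile>\n")
  print(as.data.frame(x$per_component), row.names = FALSE)
  cat(sprintf("max simultaneous items (non-partial): %d | total: %d\n",
              x$max_simultaneous, x$total))
  invisible(x)
}

#' @method tidy hh_load_profile
#' @export
tidy.hh_load_profile <- function(x, ...) {
  x$per_component
}

#' @method glance hh_load_profile
#' @export
glance.hh_load_profile <- function(x, ...) {
  tibble::tibble(
    max_simultaneous = x$max_simultaneous,
    total = x$total,
    n_components = nrow(x$per_component)
  )
}

#' Item-by-item enumeration of the monolithic formulation
#'
#' The flat reference system declared entry by entry, so its equation and
#' variable/parameter tally is auditable data rather than a hard-coded
#' constant. Roles: `variable` (time-varying quantity), `parameter`
#' (physical constant, experiment setting, or named rate-amplitude fitting
#' constant), `equation`. Voltage-scale literals inside the shared
#' exponential forms are treated as literals of the equations and are not
#' enumerated, mirroring how uncounted literals appear inside modular
#' component equations.
#'
#' @return A tibble with columns `name`, `role`, `doc`.
#' @export
monolithic_enumeration <- function() {
  entry <- function(name, role, doc) {
    tibble::tibble(name = name, role = role, doc = doc)
  }
  dplyr::bind_rows(
    # --- time-varying quantities -------------------------------------
    entry("V", "variable", "displacement voltage"),
    entry("n", "variable", "potassium activation gate"),
    entry("m", "variable", "sodium activation gate"),
    entry("h", "variable", "sodium inactivation gate"),
    entry("i_Na", "variable", "sodium current"),
    entry("i_K", "variable", "potassium current"),
    entry("i_L", "variable", "leak current"),
    entry("i_ion", "variable", "total ionic current"),
    entry("alpha_n", "variable", "potassium gate opening rate"),
    entry("beta_n", "variable", "potassium gate closing rate"),
    entry("alpha_m", "variable", "sodium activation opening rate"),
    entry("beta_m", "variable", "sodium activation closing rate"),
    entry("alpha_h", "variable", "sodium inactivation opening rate"),
    entry("beta_h", "variable", "sodium inactivation closing rate"),
    entry("phi", "variable", "temperature factor of the gating rates"),
    # --- parameters ----------------------------------------------------
    entry("C", "parameter", "membrane capacitance"),
    entry("g_Na", "parameter", "maximum sodium conductance"),
    entry("g_K", "parameter", "maximum potassium conductance"),
    entry("g_L", "parameter", "leak conductance"),
    entry("V_Na", "parameter", "sodium reversal potential"),
    entry("V_K", "parameter", "potassium reversal potential"),
    entry("V_L", "parameter", "leak reversal potential"),
    entry("i_app", "parameter", "applied clamp current"),
    entry("v_init", "parameter", "initial voltage displacement"),
    entry("T", "parameter", "membrane temperature"),
    entry("T_ref", "parameter", "reference temperature of the rate fits"),
    entry("q10", "parameter", "temperature coefficient"),
    entry("a_n", "parameter", "amplitude fitting constant of alpha_n (0.01)"),
    entry("b_n", "parameter", "amplitude fitting constant of beta_n (0.125)"),
    entry("a_m", "parameter", "amplitude fitting constant of alpha_m (0.1)"),
    entry("b_m", "parameter", "amplitude fitting constant of beta_m (4)"),
    entry("a_h", "parameter", "amplitude fitting constant of alpha_h (0.07)"),
    entry("b_h", "parameter", "amplitude fitting constant of beta_h (1)"),
    # --- equations ----------------------------------------------------
    entry("membrane_law", "equation", "C dV/dt = i_app - i_ion"),
    entry("sodium_current", "equation", "i_Na = g_Na m^3 h (V - V_Na)"),
    entry("potassium_current", "equation", "i_K = g_K n^4 (V - V_K)"),
    entry("leak_current", "equation", "i_L = g_L (V - V_L)"),
    entry("total_current", "equation", "i_ion = i_Na + i_K + i_L"),
    entry("n_kinetics", "equation", "dn/dt = phi (alpha_n (1 - n) - beta_n n)"),
    entry("m_kinetics", "equation", "dm/dt = phi (alpha_m (1 - m) - beta_m m)"),
    entry("h_kinetics", "equation", "dh/dt = phi (alpha_h (1 - h) - beta_h h)"),
    entry("alpha_n_def", "equation", "alpha_n = a_n (V + 10) / (exp((V + 10)/10) - 1)"),
    entry("beta_n_def", "equation", "beta_n = b_n exp(V / 80)"),
    entry("alpha_m_def", "equation", "alpha_m = a_m (V + 25) / (exp((V + 25)/10) - 1)"),
    entry("beta_m_def", "equation", "beta_m = b_m exp(V / 18)"),
    entry("alpha_h_def", "equation", "alpha_h = a_h exp(V / 20)"),
    entry("beta_h_def", "equation", "beta_h = b_h / (exp((V + 30)/10) + 1)"),
    entry("phi_def", "equation", "phi = q10^((T - T_ref) / 10)")
  )
}

#' Item count of the monolithic formulation
#'
#' Tallies [monolithic_enumeration()] into the same shape as
#' [item_count()]: one row with the equation and variable/parameter counts
#' of the flat reference system presented all at once.
#'
#' @param params An [hh_parameters()] object (interface symmetry with the
#'   modular counters; the tally is purely structural).
#' @param enumeration The item enumeration to tally; exposed so that
#'   structural edits (e.g. dropping an equation) are reflected in the
#'   counts.
#' @return A one-row tibble like [item_count()].
#' @export
#' @examples
#' monolithic_count()
monolithic_count <- function(params = hh_parameters(),
                             enumeration = monolithic_enumeration()) {
  tab <- table(factor(enumeration$role,
                      levels = c("variable", "parameter", "equation")))
  tibble::tibble(
    component = "HHmonolithic",
    n_variables = as.integer(tab[["variable"]]),
    n_parameters = as.integer(tab[["parameter"]]),
    n_equations = as.integer(tab[["equation"]]),
    n_connects = 0L,
    n_items = as.integer(sum(tab))
  )
}

#' Cognitive-load reduction factor
#'
#' The total item count of the monolithic formulation (equations plus
#' variables plus parameters, all presented at once) divided by the largest
#' number of items a reader of the modular model must process
#' simultaneously.
#'
#' @param mono A one-row count from [monolithic_count()].
#' @param profile An `hh_load_profile` from [model_load_profile()].
#' @return A single number (> 1 means the modular presentation is lighter).
#' @export
#' @examples
#' reduction_factor(monolithic_count(), model_load_profile(build_hh_model()))
reduction_factor <- function(mono, profile) {
  stopifnot(inherits(profile, "hh_load_profile"))
  if (profile$max_simultaneous <= 0) {
    stop("degenerate profile: max_simultaneous must be positive", call. = FALSE)
  }
  (mono$n_equations + mono$n_variables + mono$n_parameters) /
    profile$max_simultaneous
}
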