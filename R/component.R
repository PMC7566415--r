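#' Declare a model component
#'
#' A component is a named unit declaring parameters, time-varying variables,
#' documented equations, electrical pins, temperature ports, replaceable
#' rate-function slots, and sub-components. Components are assembled into a
#' [circuit_model()] and flattened into an ODE system with [flatten()].
#'
#' Every declared item records the class that declared it (`origin`), so the
#' cognitive-load metrics in [item_count()] can attribute inherited items to
#' their base class, mirroring how a reader walks a class hierarchy.
#'
#' @param class Class name of the component (e.g. `"Gate"`).
#' @param doc Human-readable physiological description.
#' @param partial Logical; a partial component declares an unbalanced
#'   equation set and must not be instantiated directly in a model.
#' @param role Optional structural role; `"ground"` marks the extracellular
#'   reference electrode whose node is held at 0 mV.
#' @return An object of class `hh_component`, to be refined with the
#'   `add_*()` builder verbs.
#' @seealso [add_parameter()], [extend_component()], [circuit_model()]
#' @export
#' @examples
#' cap <- component("Capacitor", doc = "ideal capacitor") |>
#'   add_pin("p", "positive") |>
#'   add_pin("n", "negative")
component <- function(class, doc = "", partial = FALSE, role = NULL) {
  structure(
    list(
      class = class,
      class_chain = class,
      partial_classes = character(),
      doc = doc,
      partial = partial,
      role = role,
      parameters = list(),
      variables = list(),
      pins = list(),
      ports = list(),
      functions = list(),
      constants = list(),
      subcomponents = list(),
      equations = list(),
      connections = list(),
      bindings = list(),
      across = NULL,
      through = NULL
    ),
    class = "hh_component"
  )
}

#' Derive a component from a base component
#'
#' Inheritance-like composition: the derived component starts from a copy of
#' the base (keeping every declared item with its original `origin` class)
#' and records the new class at the head of the class chain. Items added
#' afterwards are attributed to the new class.
#'
#' @param base An `hh_component` to inherit from.
#' @param class New class name.
#' @param doc Documentation for the derived class (defaults to the base's).
#' @param partial Whether the derived component is still partial.
#' @return The derived `hh_component`.
#' @export
extend_component <- function(base, class, doc = NULL, partial = FALSE) {
  stopifnot(inherits(base, "hh_component"))
  out <- base
  if (base$partial) {
    out$partial_classes <- unique(c(out$partial_classes, base$class))
  }
  out$class <- class
  out$class_chain <- c(class, base$class_chain)
  out$partial <- partial
  if (!is.null(doc)) out$doc <- doc
  out
}

check_name_free <- function(comp, name) {
  taken <- c(names(comp$parameters), names(comp$variables), names(comp$pins),
             names(comp$ports), names(comp$functions), names(comp$subcomponents))
  if (name %in% taken) {
    stop(sprintf("name '%s' is already declared in component '%s'", name, comp$class),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Builder verbs for component declarations
#'
#' Each verb returns the modified component so declarations chain with the
#' pipe. Declared items carry units and docstrings and remember the class
#' that declared them.
#'
#' @param comp An `hh_component`.
#' @param name Item name, unique within the component.
#' @param value Parameter value (a numeric constant).
#' @param unit Unit string (informational; the package fixes ms, mV,
#'   uA/cm2, mS/cm2, uF/cm2, degC).
#' @param doc Docstring describing the physiological meaning.
#' @return The modified `hh_component`.
#' @name component-builders
NULL

#' @rdname component-builders
#' @export
add_parameter <- function(comp, name, value, unit = "", doc = "") {
  check_name_free(comp, name)
  comp$parameters[[name]] <- list(value = value, unit = unit, doc = doc,
                                  origin = comp$class)
  comp
}

#' @rdname component-builders
#' @export
add_variable <- function(comp, name, unit = "", doc = "") {
  check_name_free(comp, name)
  comp$variables[[name]] <- list(unit = unit, doc = doc, origin = comp$class)
  comp
}

#' @rdname component-builders
#' @param polarity `"positive"` (extracellular side) or `"negative"`
#'   (intracellular side); fixed at declaration.
#' @export
add_pin <- function(comp, name, polarity = c("positive", "negative"),
                    doc = "") {
  polarity <- match.arg(polarity)
  check_name_free(comp, name)
  comp$pins[[name]] <- list(polarity = polarity, doc = doc, origin = comp$class)
  comp
}

#' @rdname component-builders
#' @param direction `"input"` or `"output"`; an input must be bound to
#'   exactly one output in a valid model, an output may fan out.
#' @export
add_port <- function(comp, name, direction = c("input", "output"), doc = "") {
  direction <- match.arg(direction)
  check_name_free(comp, name)
  comp$ports[[name]] <- list(direction = direction, doc = doc,
                             origin = comp$class)
  comp
}

#' @rdname component-builders
#' @param fit An `hh_fit` rate function (see [fit_exponential()]); stored in
#'   a replaceable slot and counted as a variable by the metrics engine.
#' @export
add_function <- function(comp, name, fit, doc = "") {
  check_name_free(comp, name)
  stopifnot(is.function(fit))
  comp$functions[[name]] <- structure(fit, doc = doc, origin = comp$class)
  comp
}

#' @rdname component-builders
#' @param sub An `hh_component` instantiated as a sub-component.
#' @export
add_subcomponent <- function(comp, name, sub) {
  check_name_free(comp, name)
  stopifnot(inherits(sub, "hh_component"))
  sub$declared_origin <- comp$class
  comp$subcomponents[[name]] <- sub
  comp
}

#' @rdname component-builders
#' @param const Uncounted literal constant of an equation (e.g. the Q10 of a
#'   rate law), analogous to a numeric literal in the equation text.
#' @export
add_constant <- function(comp, name, const) {
  comp$constants[[name]] <- const
  comp
}

#' Declare a component equation
#'
#' Equations are stored as named, documented entries so the metrics module
#' can count them. `kind` distinguishes differential equations, counted
#' algebraic relations, and alias definitions (pure renamings such as
#' `v = p.v - n.v`) which are excluded from equation counts.
#'
#' Non-structural equations are assignments: `fn(deps, pars, fns)` receives
#' the dependency values (named by their local qualified names), the
#' component's parameter values, and its rate-function slots, and returns
#' the value of `target`. Structural equations (Kirchhoff balances, pin
#' potential/current aliases, ground) are enforced by the flattener itself
#' and carry no evaluator.
#'
#' @param comp An `hh_component`.
#' @param name Equation name.
#' @param kind `"differential"`, `"algebraic"`, or `"alias"`.
#' @param target Local qualified name the equation determines (for a
#'   differential equation, the state variable).
#' @param depends Character vector of local qualified names the right-hand
#'   side reads (e.g. `"v"`, `"p.v"`, `"gate_act.n"`).
#' @param fn Evaluator `function(deps, pars, fns)`; `NULL` for structural
#'   equations.
#' @param doc Docstring.
#' @param structural Logical; see Details.
#' @param init_fn For differential equations: `function(comp)` returning the
#'   initial value of the state (evaluated at flattening).
#' @return The modified `hh_component`.
#' @export
add_equation <- function(comp, name, kind = c("algebraic", "differential", "alias"),
                         target = NULL, depends = character(), fn = NULL,
                         doc = "", structural = FALSE, init_fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "differential" && is.null(init_fn)) {
    stop("a differential equation needs an `init_fn` for its state", call. = FALSE)
  }
  comp$equations[[length(comp$equations) + 1L]] <- list(
    name = name, kind = kind, target = target, depends = depends, fn = fn,
    doc = doc, structural = structural, init_fn = init_fn, origin = comp$class
  )
  comp
}

#' @rdname component-builders
#' @param a,b Local qualified pin names joined by an internal electrical
#'   connection (e.g. `"p"`, `"source.n"`).
#' @export
add_internal_connection <- function(comp, a, b) {
  comp$connections[[length(comp$connections) + 1L]] <-
    list(a = a, b = b, origin = comp$class)
  comp
}

#' @rdname component-builders
#' @param to,from Local qualified names: `to` (an own sub-component input
#'   slot) is defined equal to `from` at all times. Counted as a connect
#'   equation by the metrics engine.
#' @export
add_binding <- function(comp, to, from) {
  comp$bindings[[length(comp$bindings) + 1L]] <-
    list(to = to, from = from, origin = comp$class)
  comp
}

#' Override the value of an inherited parameter
#'
#' Changing the value of a parameter declared by a base class is a modifier,
#' not a new declaration: the item keeps its original `origin` for counting.
#'
#' @param comp An `hh_component`.
#' @param name Parameter name (must already be declared).
#' @param value New value.
#' @return The modified `hh_component`.
#' @export
set_parameter_value <- function(comp, name, value) {
  if (is.null(comp$parameters[[name]])) {
    stop(sprintf("parameter '%s' is not declared in '%s'", name, comp$class),
         call. = FALSE)
  }
  comp$parameters[[name]]$value <- value
  comp
}

#' Replace an inherited rate-function slot
#'
#' Redeclaration of a replaceable function (e.g. choosing the goldman form
#' for a gate's opening rate); the slot keeps its original `origin`.
#'
#' @inheritParams set_parameter_value
#' @param fit New `hh_fit` function.
#' @return The modified `hh_component`.
#' @export
set_function <- function(comp, name, fit) {
  if (is.null(comp$functions[[name]])) {
    stop(sprintf("function slot '%s' is not declared in '%s'", name, comp$class),
         call. = FALSE)
  }
  origin <- attr(comp$functions[[name]], "origin")
  comp$functions[[name]] <- structure(fit, origin = origin)
  comp
}

mark_across <- function(comp, v = "v", pos = "p", neg = "n", through = "i") {
  comp$across <- list(v = v, pos = pos, neg = neg)
  comp$through <- through
  comp
}

# TRUE if some non-structural equation assigns the through variable
through_defined <- function(comp) {
  if (is.null(comp$through)) return(FALSE)
  any(vapply(comp$equations, function(e) {
    !e$structural && identical(e$target, comp$through)
  }, logical(1)))
}

#' @export
print.hh_component <- function(x, ...) {
  cat(sprintf("<hh_component: %s%s>\n", x$class,
              if (x$partial) " (partial)" else ""))
  if (nzchar(x$doc)) cat("  ", x$doc, "\n", sep = "")
  cat(sprintf("  pins: %s | ports: %s\n",
              paste(names(x$pins), collapse = ", "),
              paste(names(x$ports), collapse = ", ")))
  cat(sprintf("  %d parameter(s), %d variable(s), %d function slot(s), %d equation(s), %d subcomponent(s)\n",
              length(x$parameters), length(x$variables), length(x$functions),
              length(x$equations), length(x$subcomponents)))
  invisible(x)
}
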