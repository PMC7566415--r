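#' Assemble components into a circuit model
#'
#' A circuit model holds named component instances together with the
#' model-level electrical connections and temperature signal bindings.
#' Connections are added with [connect_electrical()] and [connect_signal()];
#' the model is checked with [validate_circuit()] and compiled with
#' [flatten()].
#'
#' @param ... Named `hh_component` instances.
#' @return An object of class `hh_circuit`.
#' @export
#' @examples
#' m <- circuit_model(gnd = ground_component(), src = constant_current(1))
#' m <- connect_electrical(m, "src.p", "gnd.p")
circuit_model <- function(...) {
  components <- list(...)
  if (length(components) && (is.null(names(components)) ||
                             any(!nzchar(names(components))))) {
    stop("all components must be named", call. = FALSE)
  }
  ok <- vapply(components, inherits, logical(1), what = "hh_component")
  if (!all(ok)) stop("all arguments must be hh_component objects", call. = FALSE)
  structure(
    list(components = components, electrical = list(), signals = list()),
    class = "hh_circuit"
  )
}

# Depth-first table of all component instances, named by qualified path.
walk_instances <- function(model) {
  out <- list()
  recurse <- function(prefix, comp) {
    out[[prefix]] <<- comp
    for (nm in names(comp$subcomponents)) {
      recurse(paste0(prefix, ".", nm), comp$subcomponents[[nm]])
    }
  }
  for (nm in names(model$components)) recurse(nm, model$components[[nm]])
  out
}

# Split "sodium.gate_act.n" into owner path and leaf name.
split_qualified <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  list(path = paste(parts[-length(parts)], collapse = "."),
       leaf = parts[length(parts)])
}

lookup_slot <- function(instances, qualified, slot) {
  q <- split_qualified(qualified)
  comp <- instances[[q$path]]
  if (is.null(comp)) return(NULL)
  entry <- comp[[slot]][[q$leaf]]
  if (is.null(entry)) return(NULL)
  list(path = q$path, leaf = q$leaf, comp = comp, entry = entry)
}

#' Connect two electrical pins
#'
#' Records a model-level electrical connection. All pins joined (directly or
#' transitively) share one node potential, and the flattener generates a
#' Kirchhoff current-law equation per node: the signed sum of all member pin
#' currents is zero.
#'
#' @param model An `hh_circuit`.
#' @param a,b Qualified pin names, e.g. `"bilayer.p"`.
#' @return The modified model.
#' @export
connect_electrical <- function(model, a, b) {
  stopifnot(inherits(model, "hh_circuit"))
  instances <- walk_instances(model)
  for (pin in c(a, b)) {
    if (!is.null(lookup_slot(instances, pin, "ports"))) {
      stop(sprintf("'%s' is a signal port, not an electrical pin", pin),
           call. = FALSE)
    }
    if (is.null(lookup_slot(instances, pin, "pins"))) {
      stop(sprintf("unknown pin '%s'", pin), call. = FALSE)
    }
  }
  model$electrical[[length(model$electrical) + 1L]] <- c(a = a, b = b)
  model
}

#' Connect a signal output to a signal input
#'
#' Defines the input port's value equal to the output port's value at all
#' times. One output may drive many inputs; binding an input twice is a
#' multiple-driver error.
#'
#' @param model An `hh_circuit`.
#' @param out Qualified name of an output port (e.g. `"bilayer.temp"`).
#' @param inp Qualified name of an input port.
#' @return The modified model.
#' @export
connect_signal <- function(model, out, inp) {
  stopifnot(inherits(model, "hh_circuit"))
  instances <- walk_instances(model)
  from <- lookup_slot(instances, out, "ports")
  to <- lookup_slot(instances, inp, "ports")
  if (is.null(from)) stop(sprintf("unknown port '%s'", out), call. = FALSE)
  if (is.null(to)) stop(sprintf("unknown port '%s'", inp), call. = FALSE)
  if (from$entry$direction != "output" || to$entry$direction != "input") {
    stop("signal connections must go from an output port to an input port",
         call. = FALSE)
  }
  bound <- vapply(model$signals, function(s) s[["inp"]], character(1))
  if (inp %in% bound) {
    stop(sprintf("input port '%s' already has a driver", inp), call. = FALSE)
  }
  model$signals[[length(model$signals) + 1L]] <- c(out = out, inp = inp)
  model
}

# All electrical connections, model-level plus component-internal,
# as fully qualified pin-name pairs.
all_electrical_connections <- function(model, instances = walk_instances(model)) {
  cons <- lapply(model$electrical, function(cn) c(cn[["a"]], cn[["b"]]))
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (cn in comp$connections) {
      cons[[length(cons) + 1L]] <- paste0(path, ".", c(cn$a, cn$b))
    }
  }
  cons
}

# Union-find partition of all pins. Returns a list with the pin table and
# per-pin node membership (nodes numbered in first-appearance order).
partition_pins <- function(model) {
  instances <- walk_instances(model)
  pin_names <- character()
  pin_owner <- character()
  pin_polarity <- character()
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (pn in names(comp$pins)) {
      pin_names <- c(pin_names, paste0(path, ".", pn))
      pin_owner <- c(pin_owner, path)
      pin_polarity <- c(pin_polarity, comp$pins[[pn]]$polarity)
    }
  }
  parent <- seq_along(pin_names)
  idx <- stats::setNames(seq_along(pin_names), pin_names)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (cn in all_electrical_connections(model, instances)) {
    ia <- idx[[cn[1]]]
    ib <- idx[[cn[2]]]
    if (is.null(ia) || is.null(ib) || is.na(ia) || is.na(ib)) {
      stop(sprintf("connection references unknown pin ('%s' -- '%s')",
                   cn[1], cn[2]), call. = FALSE)
    }
    ra <- find(ia); rb <- find(ib)
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_along(pin_names), find, integer(1))
  node_id <- match(root, unique(root))
  ground_owner <- vapply(instances, function(c) identical(c$role, "ground"),
                         logical(1))
  pin_is_ground_owner <- ground_owner[match(pin_owner, names(instances))]
  node_ground <- vapply(seq_len(max(node_id, 0L)), function(k) {
    any(pin_is_ground_owner[node_id == k])
  }, logical(1))
  list(
    pins = pin_names, owner = pin_owner, polarity = pin_polarity,
    node = node_id, n_nodes = length(unique(node_id)),
    node_is_ground = node_ground, instances = instances
  )
}

#' Partition electrical pins into connection nodes
#'
#' Computes the union-find partition induced by all electrical connections
#' (model-level and component-internal). Pins never mentioned in any
#' connection form singleton nodes. Each node is one electrical potential;
#' a node is a ground node if it contains a pin of a ground component.
#'
#' @param model An `hh_circuit`.
#' @return A tibble with one row per pin: `node`, `pin`, `component`,
#'   `polarity`, `is_ground`.
#' @export
partition_nodes <- function(model) {
  p <- partition_pins(model)
  tibble::tibble(
    node = p$node,
    pin = p$pins,
    component = p$owner,
    polarity = p$polarity,
    is_ground = p$node_is_ground[p$node]
  )
}

#' Count model-level connect equations
#'
#' The number of electrical pin-pair connections plus signal bindings
#' declared at the top level of the model (component-internal connections
#' are counted on their component by [item_count()]).
#'
#' @param model An `hh_circuit`.
#' @return Integer.
#' @export
count_connects <- function(model) {
  length(model$electrical) + length(model$signals)
}

# Pins of composite components that are internally wired to sub-components
# are pure junctions: they pass current through and carry none themselves.
junction_pins <- function(part) {
  instances <- part$instances
  out <- character()
  for (path in names(instances)) {
    comp <- instances[[path]]
    if (!length(comp$subcomponents) || !length(comp$connections)) next
    internal <- unlist(lapply(comp$connections, function(cn) c(cn$a, cn$b)))
    own <- intersect(internal, names(comp$pins))
    if (length(own)) out <- c(out, paste0(path, ".", own))
  }
  out
}

# Static plan for resolving node potentials from ground plus capacitive
# (state-valued) across components. Returns ordered ops or NULL if some
# node potential stays undetermined.
plan_potentials <- function(part) {
  known <- part$node_is_ground
  ops <- list()
  for (k in which(known)) ops[[length(ops) + 1L]] <- list(op = "ground", node = k)
  across <- list()
  for (path in names(part$instances)) {
    comp <- part$instances[[path]]
    if (is.null(comp$across)) next
    v_is_state <- any(vapply(comp$equations, function(e) {
      e$kind == "differential" && identical(e$target, comp$across$v)
    }, logical(1)))
    pos_pin <- paste0(path, ".", comp$across$pos)
    neg_pin <- paste0(path, ".", comp$across$neg)
    across[[length(across) + 1L]] <- list(
      path = path, v = paste0(path, ".", comp$across$v),
      pos_node = part$node[match(pos_pin, part$pins)],
      neg_node = part$node[match(neg_pin, part$pins)],
      v_is_state = v_is_state
    )
  }
  done <- rep(FALSE, length(across))
  repeat {
    progressed <- FALSE
    for (i in seq_along(across)) {
      if (done[i]) next
      a <- across[[i]]
      kp <- known[a$pos_node]; kn <- known[a$neg_node]
      if (a$v_is_state && kp && !kn) {
        ops[[length(ops) + 1L]] <- list(op = "neg_from_pos", node = a$neg_node,
                                        from = a$pos_node, v = a$v)
        known[a$neg_node] <- TRUE; done[i] <- TRUE; progressed <- TRUE
      } else if (a$v_is_state && kn && !kp) {
        ops[[length(ops) + 1L]] <- list(op = "pos_from_neg", node = a$pos_node,
                                        from = a$neg_node, v = a$v)
        known[a$pos_node] <- TRUE; done[i] <- TRUE; progressed <- TRUE
      } else if (kp && kn) {
        ops[[length(ops) + 1L]] <- list(op = "v_from_nodes", v = a$v,
                                        pos = a$pos_node, neg = a$neg_node)
        done[i] <- TRUE; progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (!all(known) || !all(done)) return(NULL)
  ops
}

# Static plan for closing Kirchhoff's current law: solve, node by node, for
# the single undetermined pin current (capacitive through currents, then the
# ground residual). Returns ordered ops or NULL if the laws are unsolvable.
plan_kcl <- function(part) {
  instances <- part$instances
  junction <- junction_pins(part)
  ground_owner <- vapply(instances, function(c) identical(c$role, "ground"),
                         logical(1))
  pin_state <- character(length(part$pins)) # "known", "unknown", "ground"
  pin_sibling <- rep(NA_integer_, length(part$pins))
  for (i in seq_along(part$pins)) {
    owner <- instances[[part$owner[i]]]
    qpin <- part$pins[i]
    if (qpin %in% junction) {
      pin_state[i] <- "known" # junction pins carry zero current
    } else if (ground_owner[[part$owner[i]]]) {
      pin_state[i] <- "ground"
    } else if (!is.null(owner$through) && through_defined(owner)) {
      pin_state[i] <- "known"
    } else if (!is.null(owner$through)) {
      pin_state[i] <- "unknown"
      others <- which(part$owner == part$owner[i] & seq_along(part$pins) != i)
      if (length(others) == 1L) pin_sibling[i] <- others
    } else {
      # pin of a composite without through semantics and without internal
      # wiring of this pin: nothing defines its current
      return(NULL)
    }
  }
  ops <- list()
  repeat {
    open_idx <- which(pin_state == "unknown")
    if (!length(open_idx)) break
    progressed <- FALSE
    for (k in unique(part$node[open_idx])) {
      members <- which(part$node == k)
      open_here <- members[pin_state[members] == "unknown"]
      ground_here <- members[pin_state[members] == "ground"]
      if (length(open_here) == 1L && !length(ground_here)) {
        i <- open_here
        ops[[length(ops) + 1L]] <- list(op = "solve_pin", pin = i,
                                        others = setdiff(members, i),
                                        owner = part$owner[i],
                                        sibling = pin_sibling[i])
        pin_state[i] <- "known"
        if (!is.na(pin_sibling[i])) pin_state[pin_sibling[i]] <- "known"
        progressed <- TRUE
      }
    }
    if (!progressed) return(NULL)
  }
  for (i in which(pin_state == "ground")) {
    members <- which(part$node == part$node[i])
    ops[[length(ops) + 1L]] <- list(op = "ground_residual", pin = i,
                                    others = setdiff(members, i))
  }
  ops
}

#' Validate a circuit model
#'
#' Checks the structural invariants a model must satisfy before flattening:
#' no partial component is instantiated, every temperature input has exactly
#' one driver, exactly one ground node fixes the potential reference, node
#' potentials are determined by the ground and the capacitive elements, and
#' every node's current law can be closed (at most one current-undetermined
#' element per node).
#'
#' @param model An `hh_circuit`.
#' @return A character vector of issues; empty when the model is valid.
#' @export
#' @examples
#' validate_circuit(build_hh_model())
validate_circuit <- function(model) {
  stopifnot(inherits(model, "hh_circuit"))
  issues <- character()
  instances <- walk_instances(model)
  for (path in names(instances)) {
    if (instances[[path]]$partial) {
      issues <- c(issues, sprintf(
        "partial component '%s' (%s) cannot be instantiated directly",
        path, instances[[path]]$class))
    }
  }
  # every input port bound exactly once (by a model signal or parent binding)
  inputs <- character()
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (pn in names(comp$ports)) {
      if (comp$ports[[pn]]$direction == "input") {
        inputs <- c(inputs, paste0(path, ".", pn))
      }
    }
  }
  drivers <- vapply(model$signals, function(s) s[["inp"]], character(1))
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (b in comp$bindings) {
      drivers <- c(drivers, paste0(path, ".", b$to))
    }
  }
  for (inp in inputs) {
    n <- sum(drivers == inp)
    if (n == 0L) {
      issues <- c(issues, sprintf("unbound temperature input '%s'", inp))
    } else if (n > 1L) {
      issues <- c(issues, sprintf("input '%s' has multiple drivers", inp))
    }
  }
  part <- partition_pins(model)
  n_ground <- sum(part$node_is_ground)
  if (length(part$pins)) {
    if (n_ground == 0L) {
      issues <- c(issues, "no ground reference")
    } else if (n_ground > 1L) {
      issues <- c(issues, "more than one ground node")
    }
  }
  if (!length(issues) && length(part$pins)) {
    if (is.null(plan_potentials(part))) {
      issues <- c(issues, "node potentials are undetermined (no capacitive/ground path)")
    }
    if (is.null(plan_kcl(part))) {
      issues <- c(issues, "current law unsatisfiable: a node has more than one current-undetermined element")
    }
  }
  issues
}

#' @export
print.hh_circuit <- function(x, ...) {
  cat(sprintf("<hh_circuit: %d component(s), %d electrical connection(s), %d signal binding(s)>\n",
              length(x$components), length(x$electrical), length(x$signals)))
  for (nm in names(x$components)) {
    cat(sprintf("  %s: %s\n", nm, x$components[[nm]]$class))
  }
  invisible(x)
}
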