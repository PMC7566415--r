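#' Flatten a circuit model into a simulatable ODE system
#'
#' Compiles a validated [circuit_model()] into a flat system by structural
#' causalization: electrical pins are partitioned into connection nodes,
#' node potentials are propagated outward from the ground reference through
#' the capacitive (state-valued) elements, the component equations are
#' ordered topologically by their declared dependencies (ties broken by
#' declaration order), branch currents are evaluated, and Kirchhoff's
#' current law closes each node by solving for the single remaining
#' undetermined pin current. Algebraic dependency cycles are rejected: the
#' supported circuit class is one capacitive node with parallel algebraic
#' branches and sources, which is loop-free.
#'
#' @param model A valid `hh_circuit`; [validate_circuit()] must return no
#'   issues.
#' @return An object of class `hh_flat_system` with elements
#'   \describe{
#'     \item{state_layout}{tibble of differential states (name, unit, doc,
#'       owning component).}
#'     \item{initial_state}{named numeric vector from each component's
#'       initialization rule.}
#'     \item{parameters}{flattened named parameter vector.}
#'     \item{rhs}{`function(t, y)` returning the state derivative vector;
#'       pure.}
#'     \item{observables}{`function(t, y)` returning all algebraic
#'       quantities (branch currents, conductances, pin potentials and
#'       currents) by qualified name; pure.}
#'     \item{nodes}{the pin/node partition as returned by
#'       [partition_nodes()].}
#'   }
#' @seealso [simulate_hh()], [build_hh_model()]
#' @export
#' @examples
#' sys <- flatten(build_hh_model())
#' sys$state_layout$state
#' sys$rhs(0, sys$initial_state)
flatten <- function(model) {
  stopifnot(inherits(model, "hh_circuit"))
  issues <- validate_circuit(model)
  if (length(issues)) {
    stop("model is not valid:\n", paste("-", issues, collapse = "\n"),
         call. = FALSE)
  }
  part <- partition_pins(model)
  instances <- part$instances

  ## ---- value registry ------------------------------------------------
  reg_names <- character()
  reg_kind <- character()
  push <- function(nms, kind) {
    reg_names <<- c(reg_names, nms)
    reg_kind <<- c(reg_kind, rep(kind, length(nms)))
  }
  for (path in names(instances)) {
    comp <- instances[[path]]
    if (length(comp$parameters)) {
      push(paste0(path, ".", names(comp$parameters)), "parameter")
    }
    if (length(comp$variables)) {
      push(paste0(path, ".", names(comp$variables)), "variable")
    }
    if (length(comp$ports)) push(paste0(path, ".", names(comp$ports)), "port")
    for (pn in names(comp$pins)) {
      push(paste0(path, ".", pn, ".", c("v", "i")), "pin")
    }
  }
  idx <- stats::setNames(seq_along(reg_names), reg_names)
  resolve <- function(path, local) {
    q <- paste0(path, ".", local)
    i <- idx[[q]]
    if (is.null(i)) stop(sprintf("unknown quantity '%s' referenced in '%s'",
                                 local, path), call. = FALSE)
    i
  }

  template <- rep(NA_real_, length(reg_names))
  params <- numeric()
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (pn in names(comp$parameters)) {
      q <- paste0(path, ".", pn)
      template[idx[[q]]] <- comp$parameters[[pn]]$value
      params[q] <- comp$parameters[[pn]]$value
    }
  }

  ## ---- differential states -------------------------------------------
  state_name <- character(); state_unit <- character()
  state_doc <- character(); state_comp <- character()
  state_idx <- integer(); init <- numeric()
  deriv_eqs <- list()
  for (path in names(instances)) {
    comp <- instances[[path]]
    for (eq in comp$equations) {
      if (eq$kind != "differential") next
      q <- paste0(path, ".", eq$target)
      state_name <- c(state_name, q)
      vinfo <- comp$variables[[eq$target]]
      state_unit <- c(state_unit, if (is.null(vinfo)) "" else vinfo$unit)
      state_doc <- c(state_doc, eq$doc)
      state_comp <- c(state_comp, path)
      state_idx <- c(state_idx, idx[[q]])
      init <- c(init, eq$init_fn(comp))
      deriv_eqs[[length(deriv_eqs) + 1L]] <- list(
        dep_idx = vapply(eq$depends, function(d) resolve(path, d), integer(1)),
        dep_names = eq$depends, fn = eq$fn,
        pars = lapply(comp$parameters, `[[`, "value"),
        fns = comp$functions
      )
    }
  }
  names(init) <- state_name

  ## ---- potential and current-law plans --------------------------------
  pot_ops_raw <- plan_potentials(part)
  kcl_ops_raw <- plan_kcl(part)
  v_idx_of <- function(q) idx[[q]] # across v variables are registry entries
  pot_ops <- lapply(pot_ops_raw, function(op) {
    if (!is.null(op$v)) op$v_idx <- v_idx_of(op$v)
    op
  })
  pin_v_idx <- vapply(part$pins, function(p) idx[[paste0(p, ".v")]], integer(1))
  pin_i_idx <- vapply(part$pins, function(p) idx[[paste0(p, ".i")]], integer(1))

  junction <- junction_pins(part)
  junction_i_idx <- pin_i_idx[match(junction, part$pins)]

  through_ops <- list()
  unknown_through <- character()
  for (path in names(instances)) {
    comp <- instances[[path]]
    if (is.null(comp$through)) next
    i_idx <- idx[[paste0(path, ".", comp$through)]]
    np <- paste0(path, ".", comp$across$neg)
    pp <- paste0(path, ".", comp$across$pos)
    entry <- list(i = i_idx,
                  n_i = pin_i_idx[match(np, part$pins)],
                  p_i = pin_i_idx[match(pp, part$pins)])
    if (through_defined(comp)) {
      through_ops[[length(through_ops) + 1L]] <- entry
    } else {
      unknown_through[path] <- path
    }
  }

  kcl_ops <- lapply(kcl_ops_raw, function(op) {
    op$pin_i <- pin_i_idx[op$pin]
    op$others_i <- pin_i_idx[op$others]
    if (op$op == "solve_pin") {
      owner <- instances[[op$owner]]
      op$i_idx <- idx[[paste0(op$owner, ".", owner$through)]]
      neg_pin <- paste0(op$owner, ".", owner$across$neg)
      op$is_neg <- identical(part$pins[op$pin], neg_pin)
      op$sibling_i <- if (!is.na(op$sibling)) pin_i_idx[op$sibling] else NA_integer_
    }
    op
  })

  ## ---- topological plan for algebraic/alias equations -----------------
  topo_raw <- list()
  for (path in names(instances)) {
    comp <- instances[[path]]
    pars <- lapply(comp$parameters, `[[`, "value")
    for (eq in comp$equations) {
      if (eq$kind == "differential" || eq$structural) next
      topo_raw[[length(topo_raw) + 1L]] <- list(
        label = paste0(path, ":", eq$name),
        target = resolve(path, eq$target),
        dep_idx = vapply(eq$depends, function(d) resolve(path, d), integer(1)),
        dep_names = eq$depends, fn = eq$fn, pars = pars, fns = comp$functions
      )
    }
    for (b in comp$bindings) {
      topo_raw[[length(topo_raw) + 1L]] <- list(
        label = paste0(path, ":bind:", b$to),
        target = resolve(path, b$to),
        dep_idx = resolve(path, b$from),
        dep_names = b$from, fn = NULL, pars = NULL, fns = NULL
      )
    }
  }
  for (s in model$signals) {
    topo_raw[[length(topo_raw) + 1L]] <- list(
      label = paste0("signal:", s[["inp"]]),
      target = idx[[s[["inp"]]]],
      dep_idx = idx[[s[["out"]]]],
      dep_names = s[["out"]], fn = NULL, pars = NULL, fns = NULL
    )
  }

  # values available before the topological phase runs
  known_before <- rep(FALSE, length(reg_names))
  known_before[reg_kind == "parameter"] <- TRUE
  known_before[state_idx] <- TRUE
  known_before[pin_v_idx] <- TRUE
  for (op in pot_ops) if (identical(op$op, "v_from_nodes")) {
    known_before[op$v_idx] <- TRUE
  }

  producer <- rep(NA_integer_, length(reg_names))
  for (e in seq_along(topo_raw)) producer[topo_raw[[e]]$target] <- e
  n_eq <- length(topo_raw)
  indeg <- integer(n_eq)
  consumers <- vector("list", n_eq)
  for (e in seq_along(topo_raw)) {
    for (d in topo_raw[[e]]$dep_idx) {
      if (known_before[d]) next
      p <- producer[d]
      if (is.na(p)) {
        stop(sprintf(
          "unsupported structure: '%s' depends on '%s', which no algebraic equation determines",
          topo_raw[[e]]$label, reg_names[d]), call. = FALSE)
      }
      indeg[e] <- indeg[e] + 1L
      consumers[[p]] <- c(consumers[[p]], e)
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    e <- ready[1L] # declaration order tie-break: ready is kept sorted
    ready <- ready[-1L]
    order <- c(order, e)
    for (c2 in consumers[[e]]) {
      indeg[c2] <- indeg[c2] - 1L
      if (indeg[c2] == 0L) ready <- sort(c(ready, c2))
    }
  }
  if (length(order) != n_eq) {
    cyc <- vapply(topo_raw[setdiff(seq_len(n_eq), order)], `[[`, "", "label")
    stop("algebraic loop detected (unsupported structure): ",
         paste(cyc, collapse = ", "), call. = FALSE)
  }
  topo_plan <- topo_raw[order]

  ## ---- the compiled evaluator -----------------------------------------
  node_of_pin <- part$node
  eval_all <- function(t, y) {
    vals <- template
    vals[state_idx] <- y
    pot <- rep(NA_real_, part$n_nodes)
    for (op in pot_ops) {
      switch(op$op,
        ground = { pot[op$node] <- 0 },
        neg_from_pos = { pot[op$node] <- pot[op$from] - vals[op$v_idx] },
        pos_from_neg = { pot[op$node] <- pot[op$from] + vals[op$v_idx] },
        v_from_nodes = { vals[op$v_idx] <- pot[op$pos] - pot[op$neg] }
      )
    }
    vals[pin_v_idx] <- pot[node_of_pin]
    for (eq in topo_plan) {
      if (is.null(eq$fn)) {
        vals[eq$target] <- vals[eq$dep_idx]
      } else {
        deps <- stats::setNames(as.list(vals[eq$dep_idx]), eq$dep_names)
        vals[eq$target] <- eq$fn(deps, eq$pars, eq$fns)
      }
    }
    for (op in through_ops) {
      vals[op$n_i] <- vals[op$i]
      vals[op$p_i] <- -vals[op$i]
    }
    if (length(junction_i_idx)) vals[junction_i_idx] <- 0
    for (op in kcl_ops) {
      if (op$op == "solve_pin") {
        cur <- -sum(vals[op$others_i])
        vals[op$pin_i] <- cur
        vals[op$i_idx] <- if (op$is_neg) cur else -cur
        if (!is.na(op$sibling_i)) vals[op$sibling_i] <- -cur
      } else { # ground_residual
        vals[op$pin_i] <- -sum(vals[op$others_i])
      }
    }
    vals
  }

  rhs <- function(t, y) {
    vals <- eval_all(t, y)
    vapply(deriv_eqs, function(eq) {
      deps <- stats::setNames(as.list(vals[eq$dep_idx]), eq$dep_names)
      eq$fn(deps, eq$pars, eq$fns)
    }, numeric(1))
  }

  obs_idx <- which(reg_kind != "parameter")
  observables <- function(t, y) {
    vals <- eval_all(t, y)
    stats::setNames(vals[obs_idx], reg_names[obs_idx])
  }

  structure(
    list(
      state_layout = tibble::tibble(state = state_name, unit = state_unit,
                                    doc = state_doc, component = state_comp),
      initial_state = init,
      parameters = params,
      rhs = rhs,
      observables = observables,
      nodes = partition_nodes(model),
      n_nodes = part$n_nodes,
      model = model
    ),
    class = "hh_flat_system"
  )
}

#' @export
print.hh_flat_system <- function(x, ...) {
  cat(sprintf("<hh_flat_system: %d state(s), %d node(s), %d parameter(s)>\n",
              nrow(x$state_layout), x$n_nodes, length(x$parameters)))
  cat("  states:", paste(x$state_layout$state, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the state layout of a flattened system
#'
#' @param x An `hh_flat_system`.
#' @param ... Unused.
#' @return A tibble with one row per differential state (name, unit, doc,
#'   owning component, initial value).
#' @method tidy hh_flat_system
#' @export
tidy.hh_flat_system <- function(x, ...) {
  dplyr::mutate(x$state_layout, initial = unname(x$initial_state))
}

#' One-row summary of a flattened system
#'
#' @param x An `hh_flat_system`.
#' @param ... Unused.
#' @return A tibble with `n_states`, `n_nodes`, `n_parameters`,
#'   `n_components`.
#' @method glance hh_flat_system
#' @export
glance.hh_flat_system <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$state_layout),
    n_nodes = x$n_nodes,
    n_parameters = length(x$parameters),
    n_components = length(x$model$components)
  )
}
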