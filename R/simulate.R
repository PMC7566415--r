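#' Experiment configuration
#'
#' Bundles the settings of a simulation run. `v_init`, `i_const` and
#' `temperature` default to `NULL`, meaning "use the model's parameter
#' values"; setting them overrides the corresponding parameters of a
#' membrane model built with [build_hh_model()] or [hh_monolithic()].
#'
#' @param duration Simulated time in ms (> 0).
#' @param output_step Output sampling interval in ms (> 0); the trace grid
#'   is `seq(0, duration, by = output_step)`.
#' @param v_init Initial displacement voltage in mV, or `NULL`.
#' @param i_const Clamp current in uA/cm2, or `NULL`.
#' @param temperature Membrane temperature in degrees Celsius, or `NULL`.
#' @param solver `"lsoda"` (adaptive stiff integrator, the default) or
#'   `"rk4"` (fixed-step classic Runge-Kutta, dt = 0.01 ms, bitwise
#'   reproducible).
#' @param rtol,atol Relative and absolute solver tolerances (> 0).
#' @param seed Reserved for stochastic extensions; the dynamics here are
#'   deterministic.
#' @return An object of class `hh_experiment_config`.
#' @export
experiment_config <- function(duration = 50, output_step = 0.025,
                              v_init = NULL, i_const = NULL,
                              temperature = NULL,
                              solver = c("lsoda", "rk4"),
                              rtol = 1e-8, atol = 1e-10, seed = NULL) {
  solver <- match.arg(solver)
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (!is.numeric(output_step) || output_step <= 0) {
    stop("`output_step` must be positive", call. = FALSE)
  }
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  structure(
    list(duration = duration, output_step = output_step, v_init = v_init,
         i_const = i_const, temperature = temperature, solver = solver,
         rtol = rtol, atol = atol, seed = seed),
    class = "hh_experiment_config"
  )
}

#' @export
print.hh_experiment_config <- function(x, ...) {
  cat(sprintf("<hh_experiment_config: %g ms @ %g ms, solver %s (rtol %g, atol %g)>\n",
              x$duration, x$output_step, x$solver, x$rtol, x$atol))
  ov <- c(v_init = x$v_init, i_const = x$i_const, temperature = x$temperature)
  if (length(ov)) {
    cat("  overrides:", paste(names(ov), ov, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

# shared deSolve driver; returns a matrix with a time column and one column
# per state, sampled exactly on the requested output grid
integrate_ode <- function(rhs, y0, config) {
  out_times <- seq(0, config$duration, by = config$output_step)
  if (abs(out_times[length(out_times)] - config$duration) > 1e-12) {
    out_times <- c(out_times, config$duration)
  }
  fn <- function(t, y, p) list(rhs(t, y))
  if (config$solver == "rk4") {
    dt <- 0.01
    times <- sort(unique(round(c(seq(0, config$duration, by = dt), out_times), 9)))
    sol <- deSolve::ode(y = y0, times = times, func = fn, parms = NULL,
                        method = "rk4")
    keep <- match(round(out_times, 9), sol[, "time"])
    sol <- sol[keep, , drop = FALSE]
  } else {
    sol <- deSolve::ode(y = y0, times = out_times, func = fn, parms = NULL,
                        method = "lsoda", rtol = config$rtol, atol = config$atol,
                        maxsteps = 50000)
  }
  if (nrow(sol) < length(out_times) || anyNA(sol)) {
    last_t <- if (nrow(sol)) sol[max(which(stats::complete.cases(sol))), "time"] else 0
    stop(sprintf("integration failed at t = %g ms (step rejection below minimum step)",
                 last_t), call. = FALSE)
  }
  sol
}

new_trace <- function(df, params, config, kind) {
  structure(
    tibble::as_tibble(df),
    params = params, config = config, kind = kind,
    class = c("hh_trace", class(tibble::tibble()))
  )
}

apply_overrides <- function(params, config) {
  if (!is.null(config$v_init)) params$v_init <- config$v_init
  if (!is.null(config$i_const)) params$i_const <- config$i_const
  if (!is.null(config$temperature)) params$temperature <- config$temperature
  params
}

#' Simulate a model and return a tidy trace
#'
#' Integrates a flattened circuit, a membrane model, or the monolithic
#' reference over a uniform output grid. For membrane models the returned
#' trace carries both voltage conventions (displacement `V_mV` and measured
#' `Vm_mV = E_r - V`), the three gating variables, and the three ionic
#' branch currents. Gate columns are bounded by the dynamics alone, never
#' clipped after the fact.
#'
#' @param x A model: `hh_model` (from [build_hh_model()]), `hh_monolithic`,
#'   `hh_circuit`, or `hh_flat_system`.
#' @param config An [experiment_config()].
#' @param ... Unused.
#' @return A tibble of class `hh_trace`, one row per output time.
#' @export
#' @examples
#' tr <- simulate_hh(build_hh_model(), experiment_config(duration = 20))
#' max(tr$Vm_mV)
simulate_hh <- function(x, config = experiment_config(), ...) {
  UseMethod("simulate_hh")
}

#' @export
simulate_hh.hh_model <- function(x, config = experiment_config(), ...) {
  params <- apply_overrides(attr(x, "params"), config)
  model <- build_hh_model(params)
  sys <- flatten(model)
  sol <- integrate_ode(function(t, y) sys$rhs(t, y), sys$initial_state, config)
  obs <- t(apply(sol, 1, function(row) {
    sys$observables(row[["time"]], row[-1])
  }))
  df <- tibble::tibble(
    time_ms = sol[, "time"],
    V_mV = sol[, "bilayer.v"],
    Vm_mV = to_measured_potential(sol[, "bilayer.v"], params$e_r),
    n = sol[, "potassium.gate_act.n"],
    m = sol[, "sodium.gate_act.n"],
    h = sol[, "sodium.gate_inact.n"],
    iNa_uAcm2 = obs[, "sodium.i"],
    iK_uAcm2 = obs[, "potassium.i"],
    iL_uAcm2 = obs[, "leak.i"]
  )
  new_trace(df, params, config, "modular")
}

#' @export
simulate_hh.hh_monolithic <- function(x, config = experiment_config(), ...) {
  params <- apply_overrides(x$params, config)
  y0 <- monolithic_initial_state(params, v_init = params$v_init)
  rhs <- function(t, y) monolithic_rhs(t, y, params, i_app = params$i_const)
  sol <- integrate_ode(rhs, y0, config)
  cur <- monolithic_currents(
    list(V = sol[, "V"], n = sol[, "n"], m = sol[, "m"], h = sol[, "h"]), params)
  df <- tibble::tibble(
    time_ms = sol[, "time"],
    V_mV = sol[, "V"],
    Vm_mV = to_measured_potential(sol[, "V"], params$e_r),
    n = sol[, "n"], m = sol[, "m"], h = sol[, "h"],
    iNa_uAcm2 = cur$i_na, iK_uAcm2 = cur$i_k, iL_uAcm2 = cur$i_l
  )
  new_trace(df, params, config, "monolithic")
}

#' @export
simulate_hh.hh_flat_system <- function(x, config = experiment_config(), ...) {
  if (!is.null(config$v_init) || !is.null(config$i_const) ||
      !is.null(config$temperature)) {
    stop("parameter overrides apply to membrane models; rebuild the circuit instead",
         call. = FALSE)
  }
  sol <- integrate_ode(function(t, y) x$rhs(t, y), x$initial_state, config)
  df <- tibble::as_tibble(as.data.frame(sol))
  names(df)[1] <- "time_ms"
  new_trace(df, NULL, config, "circuit")
}

#' @export
simulate_hh.hh_circuit <- function(x, config = experiment_config(), ...) {
  simulate_hh.hh_flat_system(flatten(x), config, ...)
}

#' Convert displacement voltage to measured membrane potential
#'
#' The displacement convention measures V relative to rest with opposite
#' sign; current standards plot the membrane potential as inside minus
#' outside. The conversion is `Vm = E_r - V`, its own inverse under
#' `V = E_r - Vm`.
#'
#' @param V Displacement voltage in mV (vectorized).
#' @param e_r Resting potential in mV.
#' @return Measured membrane potential in mV.
#' @export
#' @examples
#' to_measured_potential(0, -75) # resting potential
to_measured_potential <- function(V, e_r) {
  e_r - V
}

#' Compare the measured-potential columns of two traces
#'
#' @param a,b Traces from [simulate_hh()] on identical time grids.
#' @return A one-row tibble with `max_abs_diff` and `rmse` in mV.
#' @export
compare_traces <- function(a, b) {
  if (nrow(a) != nrow(b) || max(abs(a$time_ms - b$time_ms)) > 1e-9) {
    stop("traces are on different time grids", call. = FALSE)
  }
  d <- a$Vm_mV - b$Vm_mV
  tibble::tibble(max_abs_diff = max(abs(d)), rmse = sqrt(mean(d^2)))
}

#' @method glance hh_trace
#' @export
glance.hh_trace <- function(x, ...) {
  tibble::tibble(
    duration_ms = max(x$time_ms),
    n_samples = nrow(x),
    peak_Vm_mV = if ("Vm_mV" %in% names(x)) max(x$Vm_mV) else NA_real_,
    final_Vm_mV = if ("Vm_mV" %in% names(x)) x$Vm_mV[nrow(x)] else NA_real_,
    time_to_peak_ms = if ("Vm_mV" %in% names(x)) {
      x$time_ms[which.max(x$Vm_mV)]
    } else NA_real_
  )
}
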