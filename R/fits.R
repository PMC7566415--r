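#' Exponential rate fitting function
#'
#' Evaluates the exponential voltage-dependence `sy * exp(sx * x)` used for
#' several opening/closing rates of voltage-gated channels (e.g. the closing
#' rate of the potassium activation gate).
#'
#' @param x Membrane displacement voltage in mV.
#' @param sx Voltage scale in 1/mV.
#' @param sy Rate amplitude in 1/ms.
#' @return Rate in 1/ms, vectorized over `x`.
#' @seealso [logistic_fit()], [goldman_fit()], [fit_exponential()]
#' @export
#' @examples
#' exp_fit(0, 1 / 80, 0.125) # beta_n at rest
exp_fit <- function(x, sx, sy) {
  sy * exp(sx * x)
}

#' Logistic rate fitting function
#'
#' Evaluates `sy / (1 + exp(sx * (x - x0)))`, a sigmoid saturating at `sy`
#' for strongly negative `sx * (x - x0)`; used for the closing rate of the
#' sodium inactivation gate.
#'
#' @inheritParams exp_fit
#' @param x0 Midpoint voltage in mV; the output equals `sy / 2` there.
#' @return Rate in 1/ms, vectorized over `x`.
#' @export
#' @examples
#' logistic_fit(0, x0 = -30, sx = 0.1, sy = 1) # beta_h at rest
logistic_fit <- function(x, x0, sx, sy) {
  sy / (1 + exp(sx * (x - x0)))
}

#' Goldman (linoid) rate fitting function
#'
#' Evaluates `sy * (x - x0) / (exp(sx * (x - x0)) - 1)`. The singularity at
#' `x == x0` is removable; it is evaluated as the analytic limit `sy / sx`.
#' The implementation uses `expm1()` so the ratio stays accurate arbitrarily
#' close to the singular point.
#'
#' @inheritParams logistic_fit
#' @param sy Amplitude in 1/(mV*ms).
#' @return Rate in 1/ms, vectorized over `x`.
#' @export
#' @examples
#' goldman_fit(0, x0 = -10, sx = 0.1, sy = 0.01) # alpha_n at rest
#' goldman_fit(-10, x0 = -10, sx = 0.1, sy = 0.01) # the removable singularity
goldman_fit <- function(x, x0, sx, sy) {
  u <- x - x0
  out <- ifelse(u == 0, sy / sx, sy * u / expm1(sx * u))
  # expm1 underflows to u*sx for tiny arguments, so the branch join is smooth
  out
}

fit_kinds <- c("exponential", "logistic", "goldman")

new_fit <- function(kind, fn, params) {
  structure(fn, class = c("hh_fit", "function"), kind = kind, params = params)
}

#' Construct reusable rate fitting functions
#'
#' These wrap [exp_fit()], [logistic_fit()] and [goldman_fit()] with their
#' fitting parameters bound, returning a callable of the single remaining
#' voltage argument. Gates store such objects in their replaceable `fopen`
#' and `fclose` slots, so the same object defines both the dynamics and the
#' steady-state initialization of a gate.
#'
#' @param sx Voltage scale in 1/mV.
#' @param sy Amplitude (1/ms, or 1/(mV*ms) for the goldman form).
#' @param x0 Offset voltage in mV (logistic and goldman forms).
#' @return A function of class `hh_fit` mapping voltage (mV) to a rate (1/ms).
#' @export
#' @examples
#' beta_n <- fit_exponential(sx = 1 / 80, sy = 0.125)
#' beta_n(0)
fit_exponential <- function(sx, sy) {
  force(sx); force(sy)
  new_fit("exponential", function(x) exp_fit(x, sx, sy), list(sx = sx, sy = sy))
}

#' @rdname fit_exponential
#' @export
fit_logistic <- function(x0, sx, sy) {
  force(x0); force(sx); force(sy)
  new_fit("logistic", function(x) logistic_fit(x, x0, sx, sy),
          list(x0 = x0, sx = sx, sy = sy))
}

#' @rdname fit_exponential
#' @export
fit_goldman <- function(x0, sx, sy) {
  force(x0); force(sx); force(sy)
  new_fit("goldman", function(x) goldman_fit(x, x0, sx, sy),
          list(x0 = x0, sx = sx, sy = sy))
}

#' @export
print.hh_fit <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<hh_fit: %s | %s>\n", attr(x, "kind"),
              paste(names(p), unlist(p), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Classic squid-axon rate functions
#'
#' The six voltage-dependent transition rates of the original squid giant
#' axon formulation, expressed through the three fitting-function families.
#' Voltages follow the displacement convention (0 mV at rest, negative
#' during depolarization); rates are in 1/ms at the reference temperature.
#'
#' @return Named list of `hh_fit` objects: `alpha_n`, `beta_n` (potassium
#'   activation), `alpha_m`, `beta_m` (sodium activation), `alpha_h`,
#'   `beta_h` (sodium inactivation).
#' @export
#' @examples
#' r <- hh_rate_functions()
#' r$alpha_n(0)
hh_rate_functions <- function() {
  list(
    alpha_n = fit_goldman(x0 = -10, sx = 0.1, sy = 0.01),
    beta_n  = fit_exponential(sx = 1 / 80, sy = 0.125),
    alpha_m = fit_goldman(x0 = -25, sx = 0.1, sy = 0.1),
    beta_m  = fit_exponential(sx = 1 / 18, sy = 4),
    alpha_h = fit_exponential(sx = 1 / 20, sy = 0.07),
    beta_h  = fit_logistic(x0 = -30, sx = 0.1, sy = 1)
  )
}

#' Temperature scaling factor for gating kinetics
#'
#' Q10 scaling: gating transition rates are multiplied by
#' `q10 ^ ((temp - t_ref) / 10)`, so a 10 degree rise speeds kinetics by a
#' factor of `q10`.
#'
#' @param temp Temperature in degrees Celsius.
#' @param t_ref Reference temperature in degrees Celsius at which the rate
#'   amplitudes were fitted.
#' @param q10 Fold change of the rates per 10 degree increase; must be > 0.
#' @return Dimensionless multiplier.
#' @export
temperature_factor <- function(temp, t_ref, q10) {
  if (any(q10 <= 0)) stop("`q10` must be positive", call. = FALSE)
  q10^((temp - t_ref) / 10)
}

#' Steady-state open fraction of a gate
#'
#' The equilibrium of the first-order gating kinetics at a fixed voltage:
#' `fopen(v) / (fopen(v) + fclose(v))`. Gates use this at v = 0 mV (the
#' pre-stimulus holding potential) as their initial value, so a change in a
#' fitting parameter propagates into the initialization automatically.
#'
#' @param fopen,fclose Rate functions (closed-to-open and open-to-closed),
#'   e.g. from [fit_exponential()].
#' @param v Displacement voltage in mV.
#' @return Open fraction in `[0, 1]`.
#' @export
gate_steady_state <- function(fopen, fclose, v) {
  a <- fopen(v)
  b <- fclose(v)
  total <- a + b
  if (any(total <= 0)) {
    stop("degenerate rates: fopen(v) + fclose(v) must be positive", call. = FALSE)
  }
  a / total
}

#' Time derivative of a gating variable
#'
#' First-order kinetics between voltage-dependent open/close rates, scaled
#' by the temperature factor `phi`:
#' `phi * (fopen(v) * (1 - n) - fclose(v) * n)`.
#'
#' @param n Open fraction in `[0, 1]`.
#' @param v Displacement voltage in mV.
#' @param phi Dimensionless temperature factor, see [temperature_factor()].
#' @inheritParams gate_steady_state
#' @return Rate of change of `n` in 1/ms.
#' @export
gate_derivative <- function(n, v, phi, fopen, fclose) {
  phi * (fopen(v) * (1 - n) - fclose(v) * n)
}

#' Time derivative of a gate in steady-state/time-constant form
#'
#' Alternative gate parameterization via a voltage-dependent steady state
#' and time constant: `(n_inf_fn(v) - n) / tau_fn(v)`. With
#' `n_inf = fopen / (fopen + fclose)` and `tau = 1 / (fopen + fclose)` this
#' is algebraically identical to [gate_derivative()] with `phi = 1`.
#'
#' @inheritParams gate_derivative
#' @param n_inf_fn Function of voltage giving the steady-state open fraction.
#' @param tau_fn Function of voltage giving the time constant in ms; must be
#'   positive.
#' @return Rate of change of `n` in 1/ms.
#' @export
tau_inf_gate_derivative <- function(n, v, n_inf_fn, tau_fn) {
  tau <- tau_fn(v)
  if (any(tau <= 0)) stop("time constant must be positive", call. = FALSE)
  (n_inf_fn(v) - n) / tau
}

#' Channel conductances from gating variables
#'
#' Four independent gating molecules must be open for potassium conduction
#' (`g_max * n^4`); the sodium channel needs three activation molecules and
#' one non-inactivated molecule (`g_max * m^3 * h`).
#'
#' @param n,m,h Gating variables in `[0, 1]`.
#' @param g_max Maximum conductance in mS/cm2.
#' @return Conductance in mS/cm2.
#' @export
potassium_conductance <- function(n, g_max) {
  g_max * n^4
}

#' @rdname potassium_conductance
#' @export
sodium_conductance <- function(m, h, g_max) {
  g_max * m^3 * h
}
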