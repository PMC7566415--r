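# The flat reference formulation. Deliberately transcribed directly from the
# classic 1952-style equation list, with its own inline rate expressions (it
# does not call the fit-function evaluators), so that modular-vs-monolithic
# equivalence tests are a genuine cross-check rather than a tautology.

#' Monolithic reference system
#'
#' The classic flat equation system of the squid giant axon: four states
#' (displacement voltage V and gates n, m, h), the capacitor law with the
#' three ionic currents, and the six alpha/beta rate functions, written as
#' one literal block.
#'
#' @param params An [hh_parameters()] object.
#' @return An object of class `hh_monolithic` usable with [simulate_hh()].
#' @export
hh_monolithic <- function(params = hh_parameters()) {
  stopifnot(inherits(params, "hh_parameters"))
  structure(list(params = params), class = "hh_monolithic")
}

#' @export
print.hh_monolithic <- function(x, ...) {
  cat("<hh_monolithic: flat 4-state reference system (V, n, m, h)>\n")
  invisible(x)
}

# removable singularity of x / (exp(x / 10) - 1) handled via expm1
linoid10 <- function(x) ifelse(x == 0, 10, x / expm1(x / 10))

#' Right-hand side of the monolithic reference system
#'
#' Evaluates the state derivatives of the flat formulation at one state:
#' `C dV/dt = i_app - (g_Na m^3 h (V - V_Na) + g_K n^4 (V - V_K) +
#' g_l (V - V_l))` and the three first-order gate kinetics with the
#' alpha/beta rates scaled by the Q10 temperature factor.
#'
#' @param t Time in ms (the system is autonomous; present for the solver
#'   contract).
#' @param y Named state vector with entries `V`, `n`, `m`, `h`.
#' @param params An [hh_parameters()] object.
#' @param i_app Applied (clamp) current in uA/cm2, positive outward.
#' @return Named derivative vector `(V, n, m, h)` in units per ms.
#' @export
#' @examples
#' p <- hh_parameters()
#' monolithic_rhs(0, monolithic_initial_state(p, v_init = 0), p, i_app = 0)
monolithic_rhs <- function(t, y, params, i_app = params$i_const) {
  V <- y[["V"]]; n <- y[["n"]]; m <- y[["m"]]; h <- y[["h"]]
  alpha_n <- 0.01 * linoid10(V + 10)
  beta_n  <- 0.125 * exp(V / 80)
  alpha_m <- 0.1 * linoid10(V + 25)
  beta_m  <- 4 * exp(V / 18)
  alpha_h <- 0.07 * exp(V / 20)
  beta_h  <- 1 / (exp((V + 30) / 10) + 1)
  phi <- params$q10^((params$temperature - params$t_ref) / 10)
  i_na <- params$g_na * m^3 * h * (V - params$e_na)
  i_k  <- params$g_k * n^4 * (V - params$e_k)
  i_l  <- params$g_l * (V - params$e_l)
  c(
    V = (i_app - (i_na + i_k + i_l)) / params$c,
    n = phi * (alpha_n * (1 - n) - beta_n * n),
    m = phi * (alpha_m * (1 - m) - beta_m * m),
    h = phi * (alpha_h * (1 - h) - beta_h * h)
  )
}

#' Initial state of the monolithic reference system
#'
#' `V = v_init` while the gates start at their steady states for V = 0 (the
#' pre-stimulus holding potential), regardless of `v_init`: the stimulus is
#' an instantaneous displacement of the voltage with the gates still in
#' their resting configuration.
#'
#' @param params An [hh_parameters()] object.
#' @param v_init Initial displacement voltage in mV.
#' @return Named state vector `(V, n, m, h)`.
#' @export
monolithic_initial_state <- function(params, v_init = params$v_init) {
  alpha_n <- 0.01 * linoid10(10); beta_n <- 0.125
  alpha_m <- 0.1 * linoid10(25); beta_m <- 4
  alpha_h <- 0.07; beta_h <- 1 / (exp(3) + 1)
  c(
    V = v_init,
    n = alpha_n / (alpha_n + beta_n),
    m = alpha_m / (alpha_m + beta_m),
    h = alpha_h / (alpha_h + beta_h)
  )
}

#' Ionic branch currents of the monolithic system
#'
#' @param y Named state vector or a data frame of states.
#' @param params An [hh_parameters()] object.
#' @return A list with elements `i_na`, `i_k`, `i_l` in uA/cm2.
#' @keywords internal
monolithic_currents <- function(y, params) {
  V <- y[["V"]]; n <- y[["n"]]; m <- y[["m"]]; h <- y[["h"]]
  list(
    i_na = params$g_na * m^3 * h * (V - params$e_na),
    i_k  = params$g_k * n^4 * (V - params$e_k),
    i_l  = params$g_l * (V - params$e_l)
  )
}
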