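#' Classic squid-axon parameter set
#'
#' Physical constants of the original squid giant axon formulation in the
#' displacement-voltage convention (V = 0 at rest, negative during
#' depolarization; the measured membrane potential is `Vm = e_r - V`).
#'
#' The leak reversal `e_l` defaults to the value that makes the resting
#' state an exact equilibrium, `e_l = (i_K(0) + i_Na(0)) / g_l`
#' (about -10.599 mV; the historical rounded value is -10.613 mV): the leak
#' conductance was calibrated precisely so that the net ionic current
#' vanishes at rest.
#'
#' @param c Membrane capacitance, uF/cm2.
#' @param g_na,g_k,g_l Maximum conductances of the sodium, potassium and
#'   leak channels, mS/cm2.
#' @param e_na,e_k,e_l Equilibrium (reversal) displacement potentials, mV.
#'   `e_l = NULL` requests the rest-balancing default.
#' @param e_r Resting membrane potential for output conversion, mV.
#' @param temperature Membrane temperature, degrees Celsius.
#' @param t_ref Reference temperature of the rate fits, degrees Celsius.
#' @param q10 Temperature coefficient of the gating rates.
#' @param v_init Initial displacement voltage, mV; -15 mV is the canonical
#'   suprathreshold stimulus (a 15 mV depolarization).
#' @param i_const Clamp current, uA/cm2, positive outward.
#' @return A validated list of class `hh_parameters`.
#' @export
#' @examples
#' p <- hh_parameters(v_init = 0)
#' p$e_l
hh_parameters <- function(c = 1, g_na = 120, g_k = 36, g_l = 0.3,
                          e_na = -115, e_k = 12, e_l = NULL, e_r = -75,
                          temperature = 6.3, t_ref = 6.3, q10 = 3,
                          v_init = -15, i_const = 0) {
  if (c <= 0) stop("capacitance must be strictly positive", call. = FALSE)
  if (any(c(g_na, g_k, g_l) <= 0)) {
    stop("maximal conductances must be strictly positive", call. = FALSE)
  }
  if (q10 <= 0) stop("q10 must be strictly positive", call. = FALSE)
  if (is.null(e_l)) {
    r <- hh_rate_functions()
    n0 <- gate_steady_state(r$alpha_n, r$beta_n, 0)
    m0 <- gate_steady_state(r$alpha_m, r$beta_m, 0)
    h0 <- gate_steady_state(r$alpha_h, r$beta_h, 0)
    i_k0 <- potassium_conductance(n0, g_k) * (0 - e_k)
    i_na0 <- sodium_conductance(m0, h0, g_na) * (0 - e_na)
    e_l <- (i_k0 + i_na0) / g_l
  }
  structure(
    list(c = c, g_na = g_na, g_k = g_k, g_l = g_l,
         e_na = e_na, e_k = e_k, e_l = e_l, e_r = e_r,
         temperature = temperature, t_ref = t_ref, q10 = q10,
         v_init = v_init, i_const = i_const),
    class = "hh_parameters"
  )
}

#' @export
print.hh_parameters <- function(x, ...) {
  cat("<hh_parameters (displacement convention)>\n")
  cat(sprintf("  c = %g uF/cm2 | g_max Na/K/leak = %g/%g/%g mS/cm2\n",
              x$c, x$g_na, x$g_k, x$g_l))
  cat(sprintf("  v_eq Na/K/leak = %g/%g/%.6g mV | E_r = %g mV\n",
              x$e_na, x$e_k, x$e_l, x$e_r))
  cat(sprintf("  T = %g degC (ref %g, q10 %g) | v_init = %g mV | i_const = %g uA/cm2\n",
              x$temperature, x$t_ref, x$q10, x$v_init, x$i_const))
  invisible(x)
}

#' Two-pin electrical component base
#'
#' Partial base class for every element of the membrane circuit: a positive
#' (extracellular) pin, a negative (intracellular) pin, the voltage across
#' the component `v = p.v - n.v`, and the through current `i`, measured as
#' the current entering at the negative pin so that positive `i` is positive
#' outward current. Declares three equations: the current balance
#' `p.i + n.i = 0` and the two alias definitions for `v` and `i`. Partial:
#' the current-voltage relationship is left to subclasses.
#'
#' @return A partial `hh_component`.
#' @export
two_pin_component <- function() {
  component("TwoPinComponent", partial = TRUE,
            doc = "electrical component spanning the membrane") |>
    add_pin("p", "positive", doc = "extracellular pin") |>
    add_pin("n", "negative", doc = "intracellular pin") |>
    add_variable("v", "mV", "voltage across the component (p.v - n.v)") |>
    add_variable("i", "uA/cm2", "through current, positive outward") |>
    add_equation("current_balance", "algebraic", structural = TRUE,
                 doc = "p.i + n.i = 0: currents entering and leaving sum to zero") |>
    add_equation("voltage_difference", "alias", target = "v",
                 depends = c("p.v", "n.v"), structural = TRUE,
                 doc = "v = p.v - n.v") |>
    add_equation("through_current", "alias", target = "i", depends = "n.i",
                 structural = TRUE, doc = "i = n.i") |>
    mark_across()
}

#' Lipid bilayer (membrane capacitance)
#'
#' The membrane as a capacitor: `dv/dt = i / c` (with time in ms, voltage in
#' mV, current in uA/cm2 and capacitance in uF/cm2 the capacitor law needs
#' no unit prefactor). The initial displacement `v_init` emulates a short
#' initial stimulation from the holding potential V = 0. The bilayer also
#' owns the membrane temperature and publishes it on an output port.
#'
#' @param c Capacitance, uF/cm2.
#' @param v_init Initial displacement voltage, mV.
#' @param temp_m Membrane temperature, degrees Celsius.
#' @return An `hh_component` of class chain LipidBilayer -> TwoPinComponent.
#' @export
lipid_bilayer <- function(c = 1, v_init = -15, temp_m = 6.3) {
  extend_component(two_pin_component(), "LipidBilayer",
                   doc = "membrane capacitance separating inside and outside") |>
    add_parameter("c", c, "uF/cm2", "membrane capacitance") |>
    add_parameter("v_init", v_init, "mV", "initial displacement voltage") |>
    add_parameter("temp_m", temp_m, "degC", "membrane temperature") |>
    add_port("temp", "output", doc = "publishes the membrane temperature") |>
    add_equation("capacitor_law", "differential", target = "v", depends = "i",
                 fn = function(d, p, f) d$i / p$c,
                 init_fn = function(comp) comp$parameters$v_init$value,
                 doc = "c * dv/dt = i") |>
    add_equation("temperature_output", "alias", target = "temp",
                 depends = character(),
                 fn = function(d, p, f) p$temp_m,
                 doc = "temp = temp_m")
}

#' Voltage-dependent gate
#'
#' The fraction `n` of gating molecules in open conformation follows
#' first-order kinetics between the voltage-dependent rates stored in the
#' replaceable function slots `fopen` (closed to open) and `fclose` (open to
#' closed), sped up by the Q10 temperature factor. The initial value is the
#' steady state at the holding potential v = 0 mV, computed from the same
#' rate functions, so changing a fitting parameter updates the
#' initialization automatically.
#'
#' @param fopen,fclose `hh_fit` rate functions.
#' @param q10,t_ref Temperature-scaling constants of the rate law
#'   (literals of the equation, not counted parameters).
#' @param doc Physiological description.
#' @return An `hh_component` of class `Gate` with variables `n`, `v`,
#'   `temp` and function slots `fopen`, `fclose`.
#' @export
gate <- function(fopen, fclose, q10 = 3, t_ref = 6.3,
                 doc = "voltage-dependent gating molecule population") {
  force(q10); force(t_ref)
  component("Gate", doc = doc) |>
    add_variable("n", "1", "fraction of gating molecules in open conformation") |>
    add_variable("v", "mV", "input: displacement voltage sensed by the gate") |>
    add_variable("temp", "degC", "input: temperature of the membrane") |>
    add_function("fopen", fopen, doc = "rate of closed -> open transitions") |>
    add_function("fclose", fclose, doc = "rate of open -> closed transitions") |>
    add_constant("q10", q10) |>
    add_constant("t_ref", t_ref) |>
    add_equation("gating_kinetics", "differential", target = "n",
                 depends = c("n", "v", "temp"),
                 fn = function(d, p, f) {
                   gate_derivative(d$n, d$v,
                                   temperature_factor(d$temp, t_ref, q10),
                                   f$fopen, f$fclose)
                 },
                 init_fn = function(comp) {
                   gate_steady_state(comp$functions$fopen,
                                     comp$functions$fclose, 0)
                 },
                 doc = "dn/dt = phi * (fopen(v) * (1 - n) - fclose(v) * n)")
}

#' Gate in steady-state/time-constant form
#'
#' Alternative gate whose replaceable functions give the voltage-dependent
#' steady state `finf` and time constant `ftau` instead of opening/closing
#' rates: `dn/dt = phi * (finf(v) - n) / ftau(v)`. With
#' `finf = fopen / (fopen + fclose)` and `ftau = 1 / (fopen + fclose)` the
#' dynamics are identical to [gate()].
#'
#' @param finf Function of voltage giving the steady-state open fraction.
#' @param ftau Function of voltage giving the time constant in ms (> 0).
#' @inheritParams gate
#' @return An `hh_component` of class `GateTauInf`.
#' @export
gate_tau_inf <- function(finf, ftau, q10 = 3, t_ref = 6.3,
                         doc = "gate parameterized by steady state and time constant") {
  force(q10); force(t_ref)
  component("GateTauInf", doc = doc) |>
    add_variable("n", "1", "fraction of gating molecules in open conformation") |>
    add_variable("v", "mV", "input: displacement voltage sensed by the gate") |>
    add_variable("temp", "degC", "input: temperature of the membrane") |>
    add_function("finf", finf, doc = "steady-state open fraction") |>
    add_function("ftau", ftau, doc = "time constant of relaxation (ms)") |>
    add_constant("q10", q10) |>
    add_constant("t_ref", t_ref) |>
    add_equation("gating_kinetics", "differential", target = "n",
                 depends = c("n", "v", "temp"),
                 fn = function(d, p, f) {
                   temperature_factor(d$temp, t_ref, q10) *
                     tau_inf_gate_derivative(d$n, d$v, f$finf, f$ftau)
                 },
                 init_fn = function(comp) comp$functions$finf(0),
                 doc = "dn/dt = phi * (finf(v) - n) / ftau(v)")
}

#' Ion channel base classes
#'
#' `ion_channel()` is the partial base of all channels: an ohmic conductor
#' whose voltage is relative to the equilibrium potential of the transported
#' ion, `i = g * (v - v_eq)`. `gated_ion_channel()` adds the temperature
#' input required by voltage- and temperature-dependent gates.
#'
#' @return A partial `hh_component`.
#' @export
ion_channel <- function() {
  extend_component(two_pin_component(), "IonChannel", partial = TRUE,
                   doc = "conductor relative to the ionic equilibrium potential") |>
    add_variable("g", "mS/cm2", "instantaneous conductance of the channel population") |>
    add_parameter("g_max", NA_real_, "mS/cm2", "maximum conductance") |>
    add_parameter("v_eq", NA_real_, "mV", "equilibrium (reversal) displacement potential") |>
    add_equation("ohmic_current", "algebraic", target = "i",
                 depends = c("g", "v"),
                 fn = function(d, p, f) d$g * (d$v - p$v_eq),
                 doc = "i = g * (v - v_eq)")
}

#' @rdname ion_channel
#' @export
gated_ion_channel <- function() {
  extend_component(ion_channel(), "GatedIonChannel", partial = TRUE,
                   doc = "ion channel with temperature-dependent gating") |>
    add_port("temp", "input", doc = "temperature sensed by the gates")
}

#' Delayed-rectifier potassium channel
#'
#' Lets potassium cations leave the cell when open. Four gating molecules
#' must be open simultaneously: `g = g_max * n^4`.
#'
#' @param g_max Maximum conductance, mS/cm2.
#' @param v_eq Potassium equilibrium displacement potential, mV.
#' @param q10,t_ref Temperature scaling constants passed to the gate.
#' @return An `hh_component`.
#' @export
potassium_channel <- function(g_max = 36, v_eq = 12, q10 = 3, t_ref = 6.3) {
  r <- hh_rate_functions()
  extend_component(gated_ion_channel(), "PotassiumChannel",
                   doc = "delayed-rectifier potassium channel") |>
    set_parameter_value("g_max", g_max) |>
    set_parameter_value("v_eq", v_eq) |>
    add_subcomponent("gate_act", gate(r$alpha_n, r$beta_n, q10, t_ref,
                                      doc = "potassium activation gate (n)")) |>
    add_equation("open_channel_conductance", "algebraic", target = "g",
                 depends = "gate_act.n",
                 fn = function(d, p, f) potassium_conductance(d$gate_act.n, p$g_max),
                 doc = "g = g_max * n^4: four open molecules required") |>
    add_binding("gate_act.v", "v") |>
    add_binding("gate_act.temp", "temp")
}

#' Sodium channel
#'
#' Lets sodium cations enter the cell: three activation molecules (gate `m`)
#' and one non-inactivated molecule (gate `h`) are required,
#' `g = g_max * m^3 * h`.
#'
#' @inheritParams potassium_channel
#' @param v_eq Sodium equilibrium displacement potential, mV.
#' @return An `hh_component`.
#' @export
sodium_channel <- function(g_max = 120, v_eq = -115, q10 = 3, t_ref = 6.3) {
  r <- hh_rate_functions()
  extend_component(gated_ion_channel(), "SodiumChannel",
                   doc = "fast sodium channel with activation and inactivation") |>
    set_parameter_value("g_max", g_max) |>
    set_parameter_value("v_eq", v_eq) |>
    add_subcomponent("gate_act", gate(r$alpha_m, r$beta_m, q10, t_ref,
                                      doc = "sodium activation gate (m)")) |>
    add_subcomponent("gate_inact", gate(r$alpha_h, r$beta_h, q10, t_ref,
                                        doc = "sodium inactivation gate (h)")) |>
    add_equation("open_channel_conductance", "algebraic", target = "g",
                 depends = c("gate_act.n", "gate_inact.n"),
                 fn = function(d, p, f) {
                   sodium_conductance(d$gate_act.n, d$gate_inact.n, p$g_max)
                 },
                 doc = "g = g_max * m^3 * h") |>
    add_binding("gate_act.v", "v") |>
    add_binding("gate_act.temp", "temp") |>
    add_binding("gate_inact.v", "v") |>
    add_binding("gate_inact.temp", "temp")
}

#' Sodium channel with slow inactivation
#'
#' Extension of [sodium_channel()] with a second, slow inactivation gate.
#' A ratio `p_slow` determines how much of the total current is attributed
#' to slow as opposed to fast inactivation:
#' `g = g_max * m^3 * ((1 - p_slow) * h_fast + p_slow * h_slow)`.
#' With `p_slow = 0` the channel's currents are identical to the standard
#' sodium channel on any trajectory.
#'
#' @inheritParams sodium_channel
#' @param p_slow Fraction of the current governed by slow inactivation, in
#'   `[0, 1]`.
#' @param slow_fopen,slow_fclose Rate functions of the slow gate; the
#'   defaults reuse the fast-inactivation voltage dependence slowed by a
#'   factor of 100 (relaxation over seconds rather than milliseconds).
#' @return An `hh_component` of class `SlowInactivationSodiumChannel`.
#' @export
sodium_channel_slow_inactivation <- function(g_max = 120, v_eq = -115,
                                             p_slow = 0.2,
                                             slow_fopen = fit_exponential(sx = 1 / 20, sy = 0.0007),
                                             slow_fclose = fit_logistic(x0 = -30, sx = 0.1, sy = 0.01),
                                             q10 = 3, t_ref = 6.3) {
  if (p_slow < 0 || p_slow > 1) {
    stop("`p_slow` must lie in [0, 1]", call. = FALSE)
  }
  r <- hh_rate_functions()
  extend_component(gated_ion_channel(), "SlowInactivationSodiumChannel",
                   doc = "sodium channel with fast and slow inactivation") |>
    set_parameter_value("g_max", g_max) |>
    set_parameter_value("v_eq", v_eq) |>
    add_parameter("p_slow", p_slow, "1",
                  "fraction of the current subject to slow inactivation") |>
    add_subcomponent("gate_act", gate(r$alpha_m, r$beta_m, q10, t_ref,
                                      doc = "sodium activation gate (m)")) |>
    add_subcomponent("gate_inact", gate(r$alpha_h, r$beta_h, q10, t_ref,
                                        doc = "fast inactivation gate (h)")) |>
    add_subcomponent("gate_slow", gate(slow_fopen, slow_fclose, q10, t_ref,
                                       doc = "slow inactivation gate")) |>
    add_equation("open_channel_conductance", "algebraic", target = "g",
                 depends = c("gate_act.n", "gate_inact.n", "gate_slow.n"),
                 fn = function(d, p, f) {
                   p$g_max * d$gate_act.n^3 *
                     ((1 - p$p_slow) * d$gate_inact.n + p$p_slow * d$gate_slow.n)
                 },
                 doc = "g = g_max * m^3 * ((1 - p_slow) * h_fast + p_slow * h_slow)") |>
    add_binding("gate_act.v", "v") |>
    add_binding("gate_act.temp", "temp") |>
    add_binding("gate_inact.v", "v") |>
    add_binding("gate_inact.temp", "temp") |>
    add_binding("gate_slow.v", "v") |>
    add_binding("gate_slow.temp", "temp")
}

#' Leak channel
#'
#' Always-open channel maintaining the resting potential: constant
#' conductance `g = g_max`, so the branch current is exactly linear in
#' `(v - v_eq)`. Takes no temperature input.
#'
#' @param g_max Leak conductance, mS/cm2.
#' @param v_eq Leak reversal displacement potential, mV; the default is the
#'   rest-balancing value from [hh_parameters()].
#' @return An `hh_component`.
#' @export
leak_channel <- function(g_max = 0.3, v_eq = hh_parameters()$e_l) {
  extend_component(ion_channel(), "LeakChannel",
                   doc = "ungated leak channel holding the resting potential") |>
    set_parameter_value("g_max", g_max) |>
    set_parameter_value("v_eq", v_eq) |>
    add_equation("constant_conductance", "algebraic", target = "g",
                 depends = character(),
                 fn = function(d, p, f) p$g_max,
                 doc = "g = g_max: the channel is always active")
}

#' Ground reference electrode
#'
#' Fixes its node's potential to exactly 0 mV and absorbs the residual node
#' current (an ideal reference electrode).
#'
#' @return An `hh_component` with role `"ground"`.
#' @export
ground_component <- function() {
  component("Ground", role = "ground",
            doc = "extracellular reference electrode at 0 mV") |>
    add_pin("p", "positive", doc = "reference pin") |>
    add_equation("ground_potential", "algebraic", structural = TRUE,
                 doc = "p.v = 0")
}

#' Ideal constant current source
#'
#' Drives a fixed through current regardless of the voltage across it.
#'
#' @param i_const Through current, uA/cm2.
#' @return An `hh_component` of class chain ConstantCurrent ->
#'   TwoPinComponent.
#' @export
constant_current <- function(i_const = 0) {
  extend_component(two_pin_component(), "ConstantCurrent",
                   doc = "ideal current source") |>
    add_parameter("i_const", i_const, "uA/cm2", "clamp current, positive outward") |>
    add_equation("constant_current", "algebraic", target = "i",
                 depends = character(),
                 fn = function(d, p, f) p$i_const,
                 doc = "i = i_const")
}

#' Current clamp
#'
#' Experimental apparatus keeping the current through the membrane constant
#' in order to measure the voltage relative to a ground electrode. Composed
#' of a [ground_component()] (extracellular reference) and a
#' [constant_current()] source wired between the intracellular and
#' extracellular pins; the variable `v` captures the displacement voltage a
#' real clamp would measure.
#'
#' @param i_const Clamp current, uA/cm2, positive outward.
#' @return An `hh_component` of class `CurrentClamp`.
#' @export
current_clamp <- function(i_const = 0) {
  component("CurrentClamp",
            doc = "current clamp: constant current, measured voltage") |>
    add_pin("p", "positive", doc = "extracellular electrode") |>
    add_pin("n", "negative", doc = "intracellular electrode") |>
    add_variable("v", "mV", "measured displacement voltage") |>
    add_subcomponent("ground", ground_component()) |>
    add_subcomponent("source", constant_current(i_const)) |>
    add_equation("measured_voltage", "alias", target = "v",
                 depends = c("p.v", "n.v"),
                 fn = function(d, p, f) d$p.v - d$n.v,
                 doc = "v = p.v - n.v") |>
    add_internal_connection("p", "ground.p") |>
    add_internal_connection("p", "source.n") |>
    add_internal_connection("n", "source.p")
}

#' Build the full modular membrane model
#'
#' Places the five top-level components (lipid bilayer, potassium channel,
#' sodium channel, leak channel, current clamp) side by side, connects
#' positive with positive and negative with negative pins of neighboring
#' components (8 electrical connections), and binds the bilayer's
#' temperature output to the two gated channels (2 signal bindings), for 10
#' model-level connect equations in total.
#'
#' @param params An [hh_parameters()] object.
#' @return A valid `hh_circuit` of class `hh_model`; [validate_circuit()]
#'   returns no issues.
#' @export
#' @examples
#' model <- build_hh_model()
#' count_connects(model)
build_hh_model <- function(params = hh_parameters()) {
  stopifnot(inherits(params, "hh_parameters"))
  model <- circuit_model(
    bilayer = lipid_bilayer(c = params$c, v_init = params$v_init,
                            temp_m = params$temperature),
    potassium = potassium_channel(g_max = params$g_k, v_eq = params$e_k,
                                  q10 = params$q10, t_ref = params$t_ref),
    sodium = sodium_channel(g_max = params$g_na, v_eq = params$e_na,
                            q10 = params$q10, t_ref = params$t_ref),
    leak = leak_channel(g_max = params$g_l, v_eq = params$e_l),
    clamp = current_clamp(i_const = params$i_const)
  )
  model <- model |>
    connect_electrical("bilayer.p", "potassium.p") |>
    connect_electrical("potassium.p", "sodium.p") |>
    connect_electrical("sodium.p", "leak.p") |>
    connect_electrical("leak.p", "clamp.p") |>
    connect_electrical("bilayer.n", "potassium.n") |>
    connect_electrical("potassium.n", "sodium.n") |>
    connect_electrical("sodium.n", "leak.n") |>
    connect_electrical("leak.n", "clamp.n") |>
    connect_signal("bilayer.temp", "potassium.temp") |>
    connect_signal("bilayer.temp", "sodium.temp")
  attr(model, "params") <- params
  class(model) <- c("hh_model", class(model))
  model
}
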