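---
title: "Modular component-based simulation of the Hodgkin-Huxley equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular component-based simulation of the Hodgkin-Huxley equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhsim)
```

## The model

The squid giant axon generates action potentials through three ionic
conductances in an electrical analogy of the membrane: a fast sodium channel
(activation gate $m$, inactivation gate $h$), a delayed-rectifier potassium
channel (activation gate $n$), and an ungated leak. The classic flat
formulation is

$$C \frac{dV}{dt} = I - \bar g_{Na} m^3 h (V - V_{Na})
  - \bar g_K n^4 (V - V_K) - \bar g_l (V - V_l),$$

$$\frac{dx}{dt} = \phi\,[\alpha_x(V)(1 - x) - \beta_x(V)\,x],
  \qquad x \in \{n, m, h\},$$

with $\phi = Q_{10}^{(T - T_{ref})/10}$. `hhsim` implements this system
twice, deliberately:

* **modular** — as a circuit of small, biologically named components
  (`lipid_bilayer()`, `potassium_channel()`, `sodium_channel()`,
  `leak_channel()`, `current_clamp()`), each declaring its own pins, ports,
  parameters and documented equations, connected acausally and compiled by
  `flatten()`;
* **monolithic** — as one literal transcription of the flat equation list
  (`monolithic_rhs()`), which serves as an independent oracle: the two
  versions are cross-checked to agree on random states and on whole
  simulated traces. The monolithic file does not call the modular
  evaluators, so this equivalence is a genuine test, not a tautology.

## Voltage and unit conventions

All internal voltages use the *displacement* convention of the original
formulation: $V = 0$ at rest, negative during depolarization. Plots and
published traces use the measured membrane potential
$V_m = E_r - V$ with $E_r = -75$ mV. Traces always carry both columns so
either convention is testable.

Units are fixed throughout: time in ms, voltage in mV, current in
µA/cm², conductance in mS/cm², capacitance in µF/cm², temperature in °C,
rates in 1/ms. With this set the capacitor law is $dv/dt = i/C$ with no
unit prefactor (a mixed seconds/millivolt unit system would need a factor
of 1,000; we avoid it by working in milliseconds end to end).

Current signs: a pin's flow current is measured positive *into* its
component; a two-pin component's through current $i$ enters at the
negative (intracellular) pin, so positive $i$ is positive outward current.
This makes every connection node's Kirchhoff sum exactly zero and makes a
positive clamp current hyperpolarizing, as for a real outward current.

## Parameters

`hh_parameters()` carries the classic squid-axon set: $C = 1$ µF/cm²,
$\bar g_{Na}/\bar g_K/\bar g_l = 120/36/0.3$ mS/cm², reversal displacements
$V_{Na} = -115$, $V_K = +12$ mV, $T_{ref} = 6.3$ °C, $Q_{10} = 3$. The six
rate functions are expressed through three reusable fitting families —
exponential, logistic, and goldman (linoid) — with the goldman form's
removable singularity evaluated as its analytic limit $s_y/s_x$ via
`expm1()`, so rates are finite at every voltage.

One calibration deserves emphasis: the **leak reversal**. Historically the
leak parameters were chosen so that the net ionic current vanishes at rest,
and the printed value $-10.613$ mV is a rounding of that calibration. We
compute it exactly at construction time,

$$V_l = \frac{i_K(0) + i_{Na}(0)}{\bar g_l} \approx -10.5989\ \text{mV},$$

because with the rounded value the "resting" state is not an equilibrium
(residual $\approx 3\times10^{-3}$ µA/cm², i.e. a few µV of drift), which
would defeat the package's own rest-stability checks. Users can pass any
`e_l` explicitly.

The default stimulus is `v_init = -15` mV — an instantaneous 15 mV
depolarizing displacement, the canonical suprathreshold stimulus — with the
gates initialized at their $V = 0$ steady states: the displacement is
sudden, so the gates have not yet moved. Each gate computes its own initial
value from its stored rate functions (`gate_steady_state()` at $V = 0$),
which means a change in a fitting parameter propagates into the
initialization automatically instead of requiring a second manual edit.

## Flattening by structural causalization

`flatten()` compiles a connected model into an ODE system in five fixed
phases:

1. **Node partition.** Union-find over all electrical connections
   (model-level and component-internal); each node is one potential and one
   current-law equation.
2. **Potential propagation.** The single ground node is pinned to 0 mV and
   potentials propagate through components whose across-voltage is a state
   (the capacitive bilayer). Channels then read their voltage as a node
   difference. If any node potential stays undetermined, validation fails
   — this is also why a model without a ground reference is rejected
   outright rather than floating.
3. **Topological evaluation.** All non-structural algebraic and alias
   equations (rates, conductances, branch currents, signal bindings) are
   ordered by their declared dependencies; ties are broken by declaration
   order so the compiled plan is deterministic. A dependency cycle raises
   an algebraic-loop error: the supported circuit class — one capacitive
   node, parallel algebraic branches, sources — is loop-free, and we
   prefer a hard failure to a silent DAE solve.
4. **Current-law closure.** Components that define their through current
   (channels, sources) fill their pin currents; each node is then closed by
   solving for its single remaining unknown (the capacitor's current, and
   finally the ground residual). Nodes with more than one unknown are
   rejected at validation.
5. **Derivatives.** Differential equations are evaluated last, after the
   currents they consume exist.

Composite pins (the current clamp's electrodes, which are wired internally
to its ground and source sub-components) are pure junctions carrying zero
current of their own; the physical currents live on the sub-components.
With this topology the full model partitions into two membrane nodes
(extracellular, including the clamp's ground and source terminals, and
intracellular). A variant that places the ground *in series* with the
current source would add a third, clamp-internal node, but it leaves the
membrane potentials undetermined under structural causalization and is
therefore not used.

## The cognitive-load metric

The understandability claim is quantified as the number of items —
variables, parameters, equations — a reader must hold in working memory at
once. The counting convention, fixed in `item_count()`:

* only *locally declared* items count; inherited items are attributed to
  the base class the reader already studied;
* each pin, port, replaceable rate-function slot, and sub-component
  instance is one variable;
* alias definitions (pure renamings such as $v = p.v - n.v$) and
  initialization rules are not counted as equations;
* `connect` statements are counted separately as connect equations.

This is the unique convention we found consistent with three facts at
once: the gate presents 5 variables and 1 equation; every component
presents at most 2 equations and 5 variables-or-parameters; and the
two-pin base declares "three small equations" of which only the Kirchhoff
balance is a counted relation (the other two are aliases). One placement
choice follows from the 5-item bound: the clamp current `i_const` is
declared on the `constant_current()` sub-component, not on the clamp
itself, which otherwise would present six items.

```{r metrics}
profile <- model_load_profile(build_hh_model())
tidy(profile)
```

The monolithic side of the comparison is declared entry by entry in
`monolithic_enumeration()` — 15 equations and 33 variables and parameters
— so the tally is auditable data. The enumeration names one amplitude
fitting constant per rate function and treats the voltage scales inside
the shared exponential forms as literals, mirroring how uncounted literals
appear inside modular component equations (the gate's $Q_{10}$, the
historical factor-1,000). Other groupings of the fitting constants are
conceivable; this one is recorded as data precisely so it can be audited.

```{r reduction}
reduction_factor(monolithic_count(), profile)
```

## Numerical choices

* Default integrator: `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-10` — the system is stiff during the upstroke. A fixed-step
  classic RK4 (`dt = 0.01` ms) is available for bitwise-reproducible runs.
* Default trace grid: 50 ms at 0.025 ms output steps (2001 samples); the
  tests also verify that halving the output step and tightening `rtol`
  tenfold changes the trace by less than 0.01 mV on the shared grid.
* The goldman singular point is evaluated as its limit; near-singular
  arguments go through `expm1()` so the branch join is smooth to machine
  precision.
* Gate variables stay in $[0, 1]$ by the dynamics alone (nonnegative
  rates, first-order kinetics); traces are never clipped post hoc.
* Test and acceptance problem sizes — 50 ms traces, 1000-state derivative
  cross-checks, 25-state conservation sweeps — were chosen as the smallest
  sizes that exercise a full action potential and the rest plateau.

## Extensions

Two extension components demonstrate reuse of the interfaces:

* `sodium_channel_slow_inactivation()` adds a third gate and a ratio
  `p_slow` splitting the current between fast and slow inactivation,
  $g = \bar g_{Na} m^3 [(1 - p_{slow}) h_{fast} + p_{slow} h_{slow}]$.
  With `p_slow = 0` it reproduces the standard channel exactly (tested to
  1e-12); the default slow-gate rates reuse the fast-inactivation voltage
  dependence slowed 100-fold, a package choice standing in for the many
  slow-inactivation fits in the literature (relaxation over seconds).
* `gate_tau_inf()` parameterizes a gate by steady state and time constant;
  with $n_\infty = \alpha/(\alpha+\beta)$, $\tau = 1/(\alpha+\beta)$ it is
  algebraically identical to the rate-form gate, which the tests assert.

The temperature factor $\phi$ is evaluated inside each gate from its bound
temperature input. Computing one $\phi$ per gated channel instead would be
numerically identical (both sodium gates see the same temperature); the
in-gate form keeps the gate's published five-variable interface.

## What the checks do and do not show

The equivalence and physiology tests establish that the modular
decomposition is *functionally lossless*: same derivatives, same traces,
stable rest at $-75$ mV, a canonical action potential with peak
$V_m > 0$ returning to rest, faster kinetics when warmed. They do not
validate the model against experimental recordings — the parameter set is
the historical squid-axon fit, and no data enters the package. Likewise
the cognitive-load metric is a structural proxy (item counts under a fixed
convention), not a human-subject measurement.

Known limitations: no voltage-clamp protocols or stimulus trains; no
spatial (cable) models; no Goldman-Hodgkin-Katz flux channels, pumps, or
concentration dynamics; the flattener intentionally rejects algebraic
loops rather than solving DAEs; and the `seed` field of
`experiment_config()` is reserved — every simulation here is
deterministic.
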