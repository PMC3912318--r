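---
title: "Equation-oriented simulation: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equation-oriented simulation: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqspike)
```

## The modelling framework

`eqspike` treats a neural network model as a hybrid dynamical system:
state variables evolve continuously between events according to ordinary
or stochastic differential equations, and discontinuously at events
(spikes) according to explicit update statements. A neuron group is fully
specified by four textual components — model equations, threshold
condition, reset statements and refractoriness condition — and a synapse
store by its equations, `pre`/`post` statements and
connection-building expressions. Nothing in the package is a "built-in
neuron type"; every model is whatever its equations say.

Two deliberate restrictions keep both the syntax and the simulation
simple: a neuron has exactly two excitability states (active and
refractory), and each state has a single event type (spiking,
respectively the exit condition back to the active state). Multiple event
types, structural plasticity, heterosynaptic rules and spatially extended
morphologies are out of scope.

### Units

Every variable carries a physical dimension, stored as a vector of
rational exponents over the seven SI base dimensions; magnitudes are
base-SI doubles, and unit names (`mV`, `nS`, `umetre`, ...) exist only at
the parse/render boundary. A differential entry `dx/dt = rhs : U`
requires `rhs` to have dimension U/second — the unit after the colon is
the unit of the *variable*, not of the right-hand side. `sqrt` halves
exponents and literal powers such as `tau**-0.5` scale them, which is why
exponents are rationals rather than integers.

The white-noise symbol `xi` (and independent processes `xi_1`, `xi_2`,
...) carries dimension second^(−1/2). This is a package convention: it is
the unique choice under which an additive-noise membrane equation like
`dv/dt = -v/tau + tau**-0.5*sigma*xi : volt` (σ in volt) is dimensionally
consistent with a Wiener increment of variance dt.

One printed example in the literature of this style of documentation
(`dv/dt = 1/τm(gL(EL−v) + gs(Es−v))` annotated volt, with gL, gs in
siemens) is dimensionally inconsistent as written — the right-hand side
has dimension A/s. The documentation renderer therefore works on any
parseable model; the unit checker runs when a *group* is constructed, and
the package's own fixtures divide by a capacitance instead.

### Expressions and abstract code

Expressions use an infix grammar with `**` for powers, `%` for
mathematical modulo (non-negative result for a positive modulus — the
ring-connectivity formula depends on this), boolean `and`/`or`/`not`,
comparisons, and the closed function set `abs, floor, exp, log, sin, cos,
sqrt, clip, int, rand, randn, min, max`. There are no control structures;
conditional updates are written with `int(condition)` multipliers, e.g.
`w += 0.1*w_max*int(t < 1*second)`.

Internally expressions are base-R language objects. R's parser already
accepts `**`; unary minus in R binds more tightly than division, so
`-gs/tau_s` is `(-gs)/tau_s` — algebraically identical to the intended
`-(gs/tau_s)`, but visible in rendered output.

Every executable fragment — integrator updates, resets, synaptic
statements, state assignments — is *abstract code*: an ordered list of
`variable op expression` statements with `op` one of `=, +=, -=, *=, /=`.
Blocks execute vectorized over instances with per-instance-loop
semantics: `rand()`/`randn()` draw once per instance per occurrence, in
left-to-right order, from R's global RNG, so a seeded run is
bit-reproducible. When several instances address the same storage slot
(synapses converging on one neuron), `+=`/`-=` accumulate all
contributions via grouped sums; a plain `=` lets the highest instance
index win. In the rare corner where a slot-sharing variable is *also
read* by a later statement (or updated with `*=`/`/=`), the block falls
back to a genuine per-instance loop, whose draw order differs from the
vectorized order — none of the standard models hit this corner.

## Numerical integration

An integration scheme is itself a textual description over a generic
state `x`, e.g. the midpoint (second-order Runge–Kutta) method

```
k = dt*f(x,t)
x_new = x + dt*f(x + k/2, t + dt/2)
```

`apply_scheme()` combines a scheme with the model equations by expanding
each scheme statement componentwise over the state variables: `x` maps to
the variable, scheme temporaries map to fresh per-variable names
(`_k_v`), `x_new` maps to `_y_v`, and `f(A, B)` expands to the drift of
the variable with every state symbol substituted by the corresponding
component of `A` and `t` by `B`; copy-back statements `v = _y_v` close
the block. Because the expansion is symbolic, any explicit scheme in this
form works, including user-supplied ones (Heun's method is exercised in
the tests). Implicit and multistep methods are rejected at parse time
(`x_new`/`x_prev` may not appear on a right-hand side).

For stochastic models the right-hand sides are first split as
`rhs = f + Σ_k g_k·xi_k` by structural linear-coefficient extraction
(errors if any `xi` occurs nonlinearly). The Euler–Maruyama scheme
`x_new = x + dt*f(x,t) + g(x,t)*dW` then expands `g(·)*dW` additively
over the noise processes, with one draw `_dW_k = randn()*sqrt(dt)` per
process per step shared across all variables referencing that process
(shared noise); distinct subscripts are independent. Diffusion factors
must be state-independent — multiplicative noise is rejected rather than
silently mis-integrated, because Euler–Maruyama converges to the Itô
solution only for additive noise in this simple form.

Expected orders of accuracy (verified by the test suite against the exact
exponential): global error O(dt) for `euler`, O(dt²) for `midpoint`; the
Euler–Maruyama stationary variance of the Ornstein–Uhlenbeck fixture
carries an O(dt) bias of relative size ≈ dt/(2τ), far below the 5%
tolerance at dt = 0.1 ms, τ = 10 ms.

### Event-driven synaptic updates

A synaptic differential equation flagged `(event-driven)` must be linear
and independent, `dx/dt = a·x` with `a` state-independent (detected by
symbolic differentiation: the linear coefficient is extracted and the
residual at `x = 0` must vanish). Its value is then only needed at spike
times, so instead of integrating every step the store applies the exact
update `x ← x·exp(a·(t − lastupdate))` at the start of every `pre`/`post`
statement block and sets `lastupdate = t` at the end. A clock-driven
validation mode applies the *same* closed form every timestep; the
laziness then changes results only through floating-point accumulation
(≲ 1e-12 relative over 10⁵ steps), which is how the ≤ 1e-9 equivalence of
the two STDP formulations is tested. A forward-Euler clock-driven
comparison would differ at O(dt) and could not meet that bound.

## The simulation step

The clock is an integer step counter with `t = step·dt` exactly; the
default `dt` is 0.1 ms. Each step runs, in a fixed documented order:

1. summed variables (`(summed)` subexpressions are summed per target
   neuron and overwrite the post-synaptic variable — before integration,
   so neuron equations see this step's totals; neurons with no synapses
   get 0);
2. neuron integration (with `unless refractory` variables clamped for
   inactive neurons by save/restore around the integrator), then
   synaptic integration of non-event-driven synaptic ODEs;
3. refractory exit (the condition is re-evaluated for inactive neurons;
   false releases them);
4. spike detection (threshold over *active* neurons only — refractory
   threshold crossings are ignored);
5. synaptic propagation (per store: `pre` before `post`; this step's
   spikes are enqueued at `step + round(delay/dt)` and all effects due
   this step execute, so zero-delay effects land in the same step and are
   visible to later schedule stages);
6. reset (after propagation, so `pre` statements read pre-reset values
   of `_pre` variables), `lastspike` update, transition to refractory;
7. monitor recording;
8. clock advance.

The intra-step ordering is a package decision; where alternatives were
defensible (e.g. refractory exit before threshold rather than interleaved
with integration, pre-before-post for simultaneous spikes, reset after
propagation) the choice is fixed, documented here, and stable under
seeding. A NaN/Inf guard aborts the run naming the offending variable and
step; it can be disabled per network.

### Boundary conventions

* `lastspike` initializes to −∞, so `(t − lastspike) <= 2*ms` is false
  before the first spike.
* The refractory comparison uses exactly the user's operator. On the time
  grid the observable ISI floor for `<= R` is nominally the smallest grid
  multiple strictly greater than R; since grid times are doubles,
  `t − lastspike` at the exact boundary may round either way, so the
  floor is guaranteed only to within one dt (the acceptance criterion is
  `≥ R`, which always holds).
* Delays are rounded to the nearest grid step, ties to even.
* Connection building visits pairs row-major (`i` outer, `j` inner) and
  draws one uniform per condition-true pair in visit order — this makes
  the vectorized builder reproduce the brute-force double loop draw for
  draw under a shared seed. Conditions are evaluated against neuron state
  at connect time and never re-evaluated.

## The synthetic world of the test suite

There are no external datasets: every fixture is a model text printed in
the package (leaky integrate-and-fire variants, an additive-noise
membrane, a conductance model with named subexpressions, pair-based STDP
in differential and integrated form, NMDA-style summed conductances, gap
junctions) plus generated Poisson spike trains (50 Hz at dt = 0.1 ms,
drawn per step as Bernoulli events) and uniform spatial positions.
Parameter values follow common cortical-modelling practice: τ_m ≈ 10–20
ms, resting/reset at −70 mV, threshold −50 mV, 2 ms refractoriness, STDP
traces with τ ≈ 20 ms and ~1% weight increments.

A green suite therefore establishes that the machinery — parsing, unit
checking, symbolic scheme application, vectorized execution, event
queues, plasticity — is internally consistent and matches independent
oracles (closed-form solutions, brute-force loops, hand-computed
two-spike trajectories). It does not establish biological validity of any
particular model, and the Poisson-train fixtures do not emulate
correlated or bursty input statistics.

## Known limitations

* One integration scheme per group; no implicit, multistep or
  variable-step methods; no exact matrix-exponential integration of
  coupled linear systems (the event-driven path covers only independent
  linear equations).
* Only additive noise under Euler–Maruyama.
* Rendered loop-dialect source is for inspection and golden-file testing
  only; it is never compiled or executed.
* Abstract code has no control flow; conditionals are `int()` products.
* The `%` and integer-division corner cases of the loop dialect follow
  the mathematical-modulo convention of the host semantics (`fmod` is
  emitted; a C consumer would need a wrapper for negative operands).
* Performance is adequate for the package's purpose (10⁵-step runs with
  thousands of instances in tens of seconds) but this is a reference
  implementation in pure R, not a high-performance simulator.
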