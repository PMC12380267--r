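---
title: "Building, simulating and exporting ODE models as node graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, simulating and exporting ODE models as node graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The representation

An ordinary differential equation model is held here as a typed dataflow
graph with three node kinds:

* **Term** — a named quantity with a numeric value: one output pin, no
  input pins. Terms are the only leaves of expressions.
* **Expression** — a single operator (`add`, `subtract`, `multiply`,
  `divide`, or a user-defined extension function) over N ordered input
  pins; one output pin.
* **Assigner** — one input pin, no output pins; it binds whatever feeds
  that pin as the right-hand side of one term's ODE.

Links run strictly from an output pin to a free input pin, and a link that
would close a directed cycle is rejected at `connect()` time rather than at
validation time. The reasoning: dynamic feedback (`dI/dt` depending on `I`)
lives in expressions *referencing* term values, not in the link topology; a
link cycle could never be evaluated, so there is no legitimate model it
could express.

**State variables versus constants.** No extra annotation distinguishes
them: a term targeted by an assigner is a state variable and its value is
the initial condition; every other term is a constant. This matches the
assigner's semantics (it is what "gives the term a derivative") and makes
the classification a theorem of the graph rather than a field a user could
set inconsistently. One assigner per term is enforced at construction —
two right-hand sides for the same ODE is meaningless.

A fully disconnected term is legal (models under construction have them)
but reported as a warning by `validate_model()`, which otherwise returns
violations as data — unconnected pins, empty assigners, no state variable,
an extension operator with no loaded definition, non-finite term values —
and an empty table exactly when the model is simulatable.

# Expression semantics

An expression node with more than two inputs applies its operator as a
**left fold in pin order**: `((p1 op p2) op p3) …`, so a 3-input `subtract`
means `p1 - p2 - p3` and a 3-input `divide` means `(p1 / p2) / p3`. A
single operator with N pins needs *some* deterministic order-sensitive
rule, and the left fold is the one every infix reader already assumes.

The operator set has **no unary minus**. A pure-loss right-hand side such
as dS/dt = −b·S·I is therefore written as the subtraction fold
`(x - x) - x = -x` over the loss expression — three pins of one `subtract`
node fed by the same source. This costs one slightly redundant rendered
string for such equations but keeps the operator vocabulary to the four
binary-or-more arithmetic operators plus extensions.

**Rendering.** `render_infix()` joins operands with `" + "`, `" - "`,
`" * "`, `" / "` (single spaces, fixed so golden-string tests can be
byte-exact) and inserts parentheses where grouping requires them:
around any child of strictly lower precedence than its parent
(additive < multiplicative < leaf/extension-call), and *also* around a
same-precedence child in any non-first operand position. The second clause
is deliberate: without it `a - (b + c)` would render as `a - b + c`, which
parses back to a different value. With it, the rendered text re-parses —
in R's left-associative grammar — to exactly the tree's own evaluation
order, so rendering is injective with respect to grouping and the test
suite can check `evaluate_tree(t, b) == eval(parse(text = render_infix(t)), b)`
to machine identity rather than to a tolerance. Extension calls render as
`name(arg1, ...)` or through their display format (`"$1 ^ $2"`); their
arguments are parenthesized under the same rule, which is required for
correctness whenever a format expands to infix text.

Division by an exact zero during evaluation raises an error carrying the
rendered offending subexpression, rather than letting an `Inf` propagate
silently into the solver.

# The JSON intermediate representation

Models save to a self-contained JSON document (`format_version` "1.0",
schema in `inst/schema/model-ir.md`). Design choices:

* **Determinism**: fixed key order, node/link order = insertion order, and
  numbers written with 17 significant digits (exact double round-trip), so
  serializing twice is byte-identical and version-control diffs are
  meaningful.
* **Implicit pins**: a node's input pins are derived from kind and arity;
  links store a zero-based `destination_pin`. The R API is 1-based, with
  conversion at the IR boundary.
* **Positions are opaque**: optional `[x, y]` pairs survive the round-trip
  but are never interpreted; this package is headless.
* **Extension paths travel with the model**, conventionally relative to
  the model file's directory so a model and its plugin files can be shared
  as a folder; `load_model()` resolves them automatically.
* No claim of byte-compatibility with any other tool's format is made;
  self-consistency (round-trip identity, tested over randomized graphs) is
  the contract.

Deserialization rebuilds links through the same `connect()` checks used
interactively, so a hand-edited document cannot produce a graph violating
the structural invariants.

# Code generation

`generate_script()` emits a complete R script from a shipped template
(`inst/templates/simulation_script.R.tmpl`) via a small placeholder
engine supporting `{{value}}`, `{{#if}}/{{#else}}` and `{{#for}}` blocks —
enough to express the one genuinely conditional section (models without
constants omit the constants vector and its unpacking) and the per-variable
loops. The template is written to read as a worked example: extension
functions first, then initial conditions and constants, then a
`system(t, y, constants)` derivative function that unpacks state names and
constant names into locals before evaluating the rendered equations, then
integration, CSV output and plots. A user template must contain every
required placeholder; a missing one is reported by name.

Identifier sanitization maps display names ("S eq") to code identifiers
(`S_eq`): characters outside `[A-Za-z0-9_]` become underscores, a leading
digit **or underscore** gains an `x` prefix (R identifiers may not start
with an underscore), names that would shadow R keywords or the script's own
internals (`t`, `y`, `times`, …) get a trailing underscore, and collisions
within one model get numeric suffixes.

**Path equivalence is the central contract**: the script and
`simulate_model()` evaluate the same expressions (the rendered text parses
to the same operation sequence the tree evaluator performs), embed
constants and initial values as shortest-round-trip decimals, build the
same reporting grid, and call the same integrator with the same
tolerances — so exported and in-process trajectories agree to well below
1e-12 relative (in practice, bit-for-bit). The test suite executes every
fixture's generated script in a fresh R process and compares.

# Simulation

* **Reporting grid**: built by count, `start + k * step` for
  `k = 0..floor((end - start)/step + 1e-9)` — no floating-point
  accumulation, and the end time is included exactly when it lies on the
  grid (to within one part in 1e9 of a step). The adaptive solver's
  internal stepping is independent of this grid.
* **Solver**: `deSolve::ode` with `method = "ode45"` (adaptive explicit
  Runge–Kutta 5(4)), tolerances rel 1e-6 / abs 1e-9 by default;
  `method = "lsoda"` is available through the configuration for stiff
  parameter regimes. All tolerances are user-settable per run.
* A degenerate interval (`start == end`) returns a single row of initial
  conditions. Integration failures (non-finite solution, premature stop)
  raise a simulation error naming the failing time; exact division by zero
  inside an expression surfaces with its rendered text.
* CSV output writes each value as the shortest decimal that parses back to
  the identical double, so `read_sim_csv()` reproduces trajectories
  bit-for-bit. Reports are multi-page PDFs: one combined plot, then one
  page per state variable, with the configured axis labels.

# Extensions

Plugin files are plain R source; wrapping a function in `node()` makes it
an expression-node operator whose pin count is the function's parameter
count, with an optional display format using `$1…$n` placeholders
(repetition allowed). Files load into a fresh environment (with `node`
provided) in definition order; undecorated helper functions are not nodes
but remain callable, and the whole file text is embedded into generated
scripts so decorated functions that call helpers keep working there.
Loading executes user code — it happens only on explicit request (an
`attach_extensions()` call, a `--ext` flag, or a reference inside a model
being opened), never by directory scanning. Zero-parameter functions,
unparseable files, format placeholders beyond the arity, and duplicate
names across loaded files are all rejected at load time with specific
errors.

# The worked models and their defaults

No parameter values ship from outside; each builder's defaults are
constants of this package, chosen once so the model exhibits its
characteristic regime, and the tests assert qualitative and analytic
properties rather than any particular curve:

* **Classic SIR** (`build_sir`): b_d = 0.001, g = 0.1, (S, I, R)(0) =
  (990, 10, 0), t = 0..100 step 0.5 — a clear epidemic wave
  (basic reproduction number b_d·S0/g ≈ 9.9). S + I + R is conserved
  identically, which the suite checks to 1e-8 relative.
* **Extended SIR** (`build_extended_sir`): b = 2, b_d = 0.002,
  b_e = 5e-4, n = 0.01, g = 0.1, p = 0.1, c = 0.5, (S, I, R, E)(0) =
  (195, 5, 0, 0), t = 0..1500 — transitory oscillations damping to the
  demographic equilibrium. Summing the host equations gives
  d(S+I+R)/dt = b − n(S+I+R), so the host total must approach b/n; the
  suite verifies this within 0.5% over randomized positive parameter
  draws, integrating each draw for 20 demographic relaxation times (1/n).
* **Immune regulation** (`build_immune_model`): neutrophils N, regulatory
  macrophages M_reg, pro-inflammatory cytokines CH, anti-inflammatory
  cytokines AC and tissue damage TD after an injury TD(0) = 10. The
  anti-inflammatory inhibition enters as **division** by (1 + α·AC) on
  neutrophil recruitment and cytokine production — the reading under which
  AC actually suppresses inflammation, consistent with the model's purpose
  of showing regulated resolution — and is implemented as an extension
  node (`inhibit`, from `inst/extdata/extensions/inhibition.R`), so this
  fixture exercises the plugin path end to end. The `beta_N * N` node
  feeds both the N and TD equations, demonstrating expression fan-out.
  Defaults (β_N = 0.2, m_N = 0.1, s_N = 0.3, α = 2, γ = 0.15,
  m_Mreg = 0.05, β_C = 0.8, m_C = 0.6, β_AC = 0.5, m_AC = 0.1, k = 0.4)
  give a neutrophil surge followed by macrophage-mediated resolution: TD
  falls from 10 to below 0.2 by t = 300.
* **Predator–prey** (`build_predator_prey`): the standard Lotka–Volterra
  form with α = 2/3, β = 4/3, δ = γ = 1 and both populations at 1 —
  neutral cycles around the fixed point (γ/δ, α/β). The first integral
  δx − γ·ln x + βy − α·ln y is used as an integration-accuracy probe
  (conserved to 1e-3 relative at default tolerances, in practice far
  better).

# What the synthetic models do and do not show

These graphs emulate the *structure* of real modeling sessions — mixed
hand-built expressions, shared subexpressions, plugin operators, saved and
reloaded files — and their dynamics have known analytic handles
(conservation laws, closed forms, steady states, first integrals) that make
correctness checkable. They do not contain measurement noise, fitted
parameters or experimental data, so passing tests demonstrates that model
construction, serialization, code generation and integration are correct
and mutually consistent — not that any particular biological parameter set
is realistic. Problem sizes in the test suite (grids of 50–1500 points,
100 randomized graphs, 500 randomized expression trees) were chosen as
comfortably representative of interactive modeling practice.

# Known limitations

* No symbolic simplification, differentiation or constant folding;
  rendered equations are exactly what the graph says, including the
  `x - x - x` idiom for pure-loss terms.
* Expressions are interpreted (tree-walking) during in-process simulation;
  for the model sizes this tool targets that is far from a bottleneck, and
  the exported script — which runs the rendered expressions natively — is
  the path for anything heavy.
* An extension display format that expands to low-precedence infix text is
  embedded as an atom; with repeated placeholders and unparenthesized
  formats a user can construct misleading renderings (evaluation is
  unaffected).
* Events, delays, stochastic simulation and parameter estimation are out
  of scope.
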