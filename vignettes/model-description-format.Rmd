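---
title: "A computational-graph model description format: design and semantics"
author: "mdfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A computational-graph model description format: design and semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfr)
```

## Motivation and scope

Computational models in neuroscience, cognitive science and machine
learning are built in mutually incompatible environments, which makes
moving a model from one community to another a manual reimplementation
exercise. `mdfr` implements a serializable *model description format*
whose unit of exchange is a computational graph: **nodes** carry out
mathematical operations, **ports** receive inputs and expose outputs,
and **edges** transmit values between ports on different nodes. The
format prioritizes *transpilation* (structure-preserving translation)
over execution efficiency: the reference engine included here exists to
define and validate the semantics of a document, not to run large
models fast.

One document format spans very different levels of analysis. The same
schema expresses a stateless tensor pipeline (a one-layer perceptron),
a conductance-style single neuron (the FitzHugh–Nagumo reduction), and
a cognitive accumulator (the drift-diffusion model); the fixture
generators in `make_fixture()` produce one of each, and the test suite
holds all of them to the same round-trip and execution guarantees.

## The document model

A `Model` holds ordered `Graph`s; a graph holds `Node`s and `Edge`s
plus an optional condition set. A node bundles:

* `input_ports` — typed attachment points for incoming edges. Multiple
  incoming edges on one port are an error unless the port declares
  `reduce = "sum"`: silent summation hides wiring bugs, but declared
  fan-in is needed for population-style models.
* `parameters` — constants, derived expressions, or *stateful* slots.
  A parameter is stateful when its value expression references its own
  id (a per-execution accumulator, `c = "c + 1"`) or when it carries a
  `time_derivative` (an ODE state variable). Stateful slots must
  declare `default_initial_value`; their previous value is always
  readable, which is what breaks intra-node reference cycles.
* `functions` — named calls into the function ontology.
* `output_ports` — expressions over node-local ids, evaluated last.
* optionally a `subgraph`, mutually exclusive with
  parameters/functions, for hierarchical composition.

Identifiers follow `[A-Za-z_][A-Za-z0-9_]*`; the dot is reserved as the
hierarchy separator, so flattened node ids such as `wrap.Q` remain
unambiguous and expressions (which only ever reference node-local ids)
never contain dots.

Cycles at the graph level are legal and deliberately so — recurrent
wiring is ubiquitous in the target domains. `validate_model()` reports
each elementary circuit at severity `"info"` and requires every
on-cycle sender port to declare `default_initial_value`, because a
cycle can only be executed from committed previous values. The severity
ladder is fixed at error/warning/info and only errors block execution
or serialization.

### Subgraph boundaries and flattening

The format needs a convention for how a wrapper node's ports attach to
its inner graph; we adopt the simplest one: a boundary port maps
one-to-one by id onto the like-named port of exactly one inner node,
and validation rejects both missing and ambiguous matches.
`flatten_hierarchy()` splices each subgraph in, prefixing child ids
with `parentid.`, rewiring boundary edges, and namespacing inner
conditions. Two design points were genuinely open:

* conditions *are* allowed inside subgraphs; flattening namespaces
  their node references. A condition attached to the wrapper node
  itself is conjoined (`and`) onto every flattened child, which
  preserves the intuition that gating a composite gates its parts.
* inner termination conditions are discarded on flattening — only the
  top-level termination governs a run. Letting nested graphs terminate
  an enclosing run would make composition non-local.

Flattening is idempotent and execution-equivalent; the suite checks
both, the latter exactly (tolerance 0).

## The expression language

The format needs a concrete grammar for the strings appearing in
parameter values, function arguments and output ports; this package
defines one and documents it as its own definition. It is a
conventional arithmetic grammar: numbers, identifiers, `+ - * / %`,
`**` (right-associative), unary minus, comparisons returning 0/1,
calls `f(a, b)`, and 1-based element indexing `x[i]`. Unary minus
binds looser than `**`, so `-2**2` is `-4`, matching the mathematical
convention (and the behaviour of the major scientific languages).
Comparisons return numbers rather than booleans to keep the value
algebra single-sorted — condition thresholds need numeric values
anyway. There is deliberately no ternary operator: branching belongs to
the condition system, mirroring the format's separation of mathematical
operations from control flow.

Values are numeric scalars and dense numeric arrays, nothing else
(strings and booleans live in metadata). Scalar–array mixes broadcast
elementwise; array–array operations require identical shapes — implicit
general broadcasting is a classic source of silent shape bugs in
translated models. Division by zero follows IEEE semantics (`Inf`/
`NaN`) instead of raising: aborting mid-sweep on a transient is hostile
for ODE parameter sweeps. The engine counts non-finite values and
raises only past a configurable limit (`nonfinite_limit`, default
1000 occurrences).

## The function ontology

`core_operator_set()` preloads a registry with a 24-operator core
(`add` … `reshape`) matching the ONNX definitions of the same names on
dense arrays, with two R-flavoured conventions stated in every doc
entry: axis arguments are 1-based, and `reshape` uses row-major element
order to match the ONNX data layout. The full non-conditional ONNX
operator catalogue is hundreds of operators; the registry's
`register_function()` extension mechanism is the documented path to
broader coverage, and the machine-readable catalogue
(`ontology_catalog()`) makes a serialized model self-describing.

Two domain integrators ship alongside the tensor core, with their
equation forms embedded in the ontology docs:

* **FitzHugh–Nagumo**: dV/dt = V − V³/3 − W + I_ext,
  dW/dt = (V + a − b·W)/τ — the standard two-variable reduction, with
  canonical defaults a = 0.7, b = 0.8, τ = 12.5. At I_ext = 0 the
  model rests at the fixed point (V\* ≈ −1.199, W\* ≈ −0.624); at
  I_ext = 0.5 it produces sustained relaxation oscillations with a
  period of roughly 39.5 model time units.
* **Drift-diffusion**: one Euler–Maruyama step
  x ← x + A·dt + c·√dt·ξ. The noise draw ξ is an *argument*, not an
  internal `rnorm()` call: every ontology function stays pure and
  unit-testable, and only the engine owns the seeded generator (the
  `random_standard_normal` entry is the engine-facing source).

The ontology exposes derivative functions for FHN but a step function
for DDM: ODE right-hand sides belong to the engine's integrator, while
a stochastic increment has no derivative form to expose.

## Scheduling: conditions and passes

Execution proceeds in *passes*. Within a pass, nodes are considered in
the graph's static order — dependency order for acyclic parts
(Kahn's algorithm with declaration-order tie-breaks), cycle members in
declaration order — and each node's condition is evaluated exactly once
per pass, in that sequence. A condition therefore sees the call counts
of nodes scheduled earlier in the same pass: a node gated by
`every_n_calls(dep, n)` fires in the same pass as the call of `dep`
that completes a group of n. There is no re-evaluation of a condition
within a pass; that would make semantics depend on evaluation order in
a way documents could not predict.

The condition vocabulary (`always`, `never`, `every_n_calls`,
`after_n_calls`, `before_n_calls`, `threshold`, `time_interval`,
`and`/`or`/`not`, `all_have_run`) is this package's concrete definition
of the format's control-flow layer, chosen as a minimal orthogonal set
spanning arbitrary execution order, multiple timescales
(`every_n_calls` makes a slow node run k-fold slower than a fast one)
and cyclic graphs.

`every_n_calls` uses per-dependent *consumption bookkeeping* rather
than a raw modulus: each completed group of n calls of the dependency
is a token, and a true evaluation consumes one token. A dependent that
is itself gated for a few passes does not miss firings — modulus
semantics would silently drop events. Consequently a node gated
`every_n_calls(d, n)` executes exactly ⌊calls(d)/n⌋ times whenever its
pending token can still be evaluated before the run ends.

Threshold conditions read the last *committed* parameter value — values
are committed at the end of a node execution, never mid-update — and
are restricted to (scalar) parameters in this version; ports would need
a convention for reduction over array values that nothing yet demands.
Termination is checked at the end of every pass, with
`all_have_run` as the default for pass-budgeted runs; timed runs
(`duration`) are governed by their duration unless the document
declares an explicit termination.

## The engine

`run_model()` couples the scheduler to a numerical evaluator. Inside a
node, slots evaluate in intra-node dependency order (topological over
free identifiers), stateful slots reading previous values; outputs and
stateful updates commit atomically at node completion. Along edges, a
node's outputs are visible to later nodes in the same pass; any value
crossing a cycle reads the previously committed value (or the sender
port's `default_initial_value` before its first execution). That
one-pass delay on cyclic edges is this package's answer to a question
the format itself leaves open, and it is what makes cyclic execution
deterministic. Unconnected input ports read 0 with a counted warning —
the common simulator convention for optional drive.

Forward Euler is the sole integrator: one scheduler pass advances every
`time_derivative` parameter by `v + dt·eval(dv/dt)` with all
right-hand sides reading pre-step values (simultaneous update), then
the clock advances by `dt`. Reference semantics must be simple and
auditable; higher-order schemes are an extension, not a default. One
pass per time step is also the simplest rule coupling condition-based
timescales to integration time. The cost is the usual order-1 accuracy:
the suite verifies the error-halving ratio on dv/dt = −v lands in
[0.4, 0.6] as dt halves, and that an FHN trajectory at dt = 0.01 stays
within 0.05 (max-abs) of `deSolve::lsoda` at tolerance 1e-10 over 100
time units (measured ≈ 0.033, dominated by phase drift near the fast
spike fronts).

Stochastic models draw only from the run-level generator seeded by
`run_model(seed = )`; identical options give bit-identical results,
and the drift-diffusion fixture reproduces the closed-form moments of
driftful Brownian motion (mean A·T, variance c²·T) over a 10,000-path
vectorized ensemble within three standard errors.

## Serialization

JSON, YAML and a binary encoding carry the *identical* document tree:

```
{"<model_id>": {"format": ..., "graphs": {...}, "metadata": {...}}}
```

Collections serialize as maps keyed by id (diff-friendly, and the
natural addressing for a graph format), with declaration order
recovered from key order. Writing is canonical — schema-defined key
order, 17-significant-digit floats — so equal models produce
byte-identical payloads and `write(read(write(m)))` is byte-identical
to `write(m)`. Non-finite doubles appear as the strings `"NaN"`,
`"Infinity"`, `"-Infinity"` in JSON (which lacks them) and natively in
YAML and binary. The binary encoding is MessagePack of the same tree —
schema-free and preserving the JSON data model — implemented here as a
small encoder/decoder covering exactly the types the tree uses. Readers
apply forward compatibility: unknown keys are preserved into the
nearest `metadata` map with a warning rather than rejected. A JSON
Schema for the document (and one for the tensor-graph dialect) ships
under `inst/schema/` and is exercised against every fixture in the
tests.

## Interchange and visualization

`to_dot()` emits deterministic Graphviz DOT (sorted components) at two
detail levels for structural inspection. The tensor-graph bridge
(`import_tensor_graph()` / `export_tensor_graph()`) demonstrates
hub-and-spoke translation against a self-defined flat JSON dialect that
uses the core operator names and semantics — deliberately not the ONNX
protobuf container, which would bind the package to a heavy dependency
for what is a semantics demonstration; a protobuf adapter is a
documented extension point. Export is *fragment-based*: it succeeds
only on acyclic, always-conditioned, stateless, core-operator models
and otherwise fails naming the offending construct, because silently
dropping semantics is precisely the failure mode a standardized format
exists to prevent. Round-trips through the bridge are
engine-equivalent to 1e-12 on random inputs.

## What the fixtures emulate — and what they do not

The seven generated fixtures are chosen to cover the format's
expressive axes (arithmetic chains, ODE state, stochastic state,
multiple timescales, cycles, hierarchy, tensor pipelines) at desk
scale: single nodes or handfuls of nodes, scalar or short-vector
state, runs of 10⁴ passes at most. Default parameters are the
canonical literature values named above (FHN a = 0.7, b = 0.8,
τ = 12.5; DDM drift 0.5, diffusion 1, T = 1 — an accumulator regime
with signal-to-noise of order 1; timescale ratio 2 for the fast/slow
demo; the perceptron weights are small fixed integers and halves so
expected outputs are exact in floating point). Passing tests show that
the *semantics* — round-tripping, scheduling, integration, moments —
are correct at this scale. They do not show that real exchanged models
(thousands of nodes, stiff dynamics, learned weights) are practical in
this reference engine, and make no claim about translation fidelity to
any external tool's execution semantics.

Problem sizes used by the checks: 1000 random expressions (depth ≤ 5)
against a base-R evaluation oracle; 100 random arrays per core
operator against naive-loop oracles; 50 random condition sets per
fixture against a brute-force replay oracle; 10,000 drift-diffusion
paths; FHN to t = 100 at dt = 0.01 (10⁴ Euler steps).

## Numerical choices and degenerate inputs

* Ties in scheduling are always broken by declaration order; no
  randomness anywhere outside `random_standard_normal`.
* `%` follows R's `%%` (sign of the divisor); `**` is `^`.
* Comparisons on arrays compare elementwise and return 0/1 arrays of
  the broadcast shape.
* Empty graphs are valid and validate vacuously; an empty pass (no
  satisfied conditions) still counts against the pass budget, since
  clock- or count-gated conditions may fire later.
* A length-1 numeric is canonically a scalar; deliberate 1-element
  arrays degrade to scalars on serialization. This is the usual
  trade-off for human-readable encodings without type tags.
* `max_passes` is mandatory (directly or via `duration`) so
  non-terminating schedules always end in a reported
  `budget_exhausted` outcome rather than a hang.

## Known limitations

* Forward Euler only; stiff systems need small `dt`.
* `threshold` conditions cannot reference ports, and condition
  evaluation is pass-granular by design.
* The exportable tensor fragment excludes stateful and conditioned
  models by construction.
* No schema migration between format versions, no streaming parsing,
  and no training/parameterization protocol layer — the format scope
  is the model itself.
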