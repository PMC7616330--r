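# mdfr — a serializable computational-graph model description format

Computational models of brain and cognition live in siloed software:
biophysical neuron models in simulator-specific environments, cognitive
accumulators in bespoke code, machine-learning networks in tensor
frameworks. Moving a model between communities usually means
reimplementing it by hand. `mdfr` implements a *model description
format* for exchanging such models in machine-readable form: a model is
a computational graph in which **nodes** carry out mathematical
operations through **input/output ports**, **edges** transmit values
between ports, and a declarative **condition** layer specifies
arbitrary execution order — multiple timescales, cyclic wiring,
hierarchical (nested) structure. Documents serialize losslessly to
JSON, YAML or a binary (MessagePack) encoding; a reference execution
engine defines and validates the runtime semantics.

The package is aimed at tool builders and modellers who need a neutral,
inspectable interchange layer rather than another simulator: the engine
is deliberately simple (forward Euler, pass-based scheduling,
sequential evaluation) so that the semantics of a document are
auditable.

What is in the box:

* **Schema & validation** — constructors (`mdf_model()`, `mdf_node()`,
  `mdf_edge()`, …), `validate_model()` (full invariant report),
  `detect_cycles()`, `flatten_hierarchy()`.
* **Expression language** — `parse_expression()`,
  `evaluate_expression()`, `free_identifiers()`; numbers, arithmetic,
  comparisons (0/1), calls, indexing.
* **Function ontology** — `core_operator_set()` with a 24-operator
  tensor core matching the same-named ONNX operator definitions, plus
  FitzHugh–Nagumo derivatives and a drift-diffusion Euler–Maruyama
  step; extensible via `register_function()`, exportable as a JSON
  catalogue (`ontology_catalog()`).
* **Scheduler** — condition vocabulary (`cond_always()`,
  `cond_every_n_calls()`, thresholds, boolean composites, …),
  `next_execution_set()`, `run_schedule()`.
* **Engine** — `run_model()` / `evaluate_node()` / `step_time()`:
  dependency-ordered evaluation, atomic state commits, forward-Euler
  integration of `time_derivative` parameters, seeded stochastics,
  per-slot recording with CSV export.
* **Serialization** — `write_model()`, `read_model()`,
  `convert_model()`: canonical, byte-stable, bit-exact doubles, forward
  compatible.
* **Interchange & viz** — `to_dot()` (Graphviz), and a bidirectional
  bridge to a flat tensor-graph dialect
  (`import_tensor_graph()` / `export_tensor_graph()`).
* **Fixtures & CLI** — `make_fixture()` generates seven demo models
  spanning the format's range; `mdf_cli()` (wrapped by `inst/cli/mdf`)
  provides `validate | run | convert | graph | functions | fixture`.

## The models at its core

A FitzHugh–Nagumo neuron is a single node with two ODE-state
parameters,

    dV/dt = V − V³/3 − W + I_ext        (fast, voltage-like)
    dW/dt = (V + a − b·W)/τ             (slow recovery)

with canonical a = 0.7, b = 0.8, τ = 12.5. A drift-diffusion
accumulator is a stateful parameter updated by
x ← x + A·dt + c·√dt·ξ with ξ ~ N(0,1) drawn from the run-seeded
generator. A perceptron layer is three nodes applying
`matmul`, `add`, `relu`. All three are ordinary documents in the same
schema.

## Worked example

```r
library(mdfr)

m <- make_fixture("fhn_neuron", I_ext = 0.5)   # suprathreshold drive
m
#> <mdf model 'fhn_neuron'> (MDF v0.1), 1 graph(s)
#>   graph 'main': 1 node(s), 0 edge(s)

res <- run_model(m, dt = 0.01, duration = 100, record = "fhn/V")
res
#> <run result> outcome: terminated; 10000 executions; clock: 100

V <- unlist(res$recorded[["fhn/V"]]$values)
t <- res$recorded[["fhn/V"]]$clock
peaks <- which(diff(sign(diff(V))) == -2) + 1
round(t[peaks][V[peaks] > 1], 1)
#> [1]  2.9 45.7 85.2
range(V)
#> [1] -1.972 2.109
```

The run integrates the two-variable neuron for 100 model time units at
dt = 0.01. Under I_ext = 0.5 the neuron fires regularly: three spikes
(V rising above 1, peaking near 2.1) about 39.5 time units apart — a
relaxation oscillation, the fast variable V swinging between its two
branches while W slowly recovers. At `I_ext = 0` the same document
settles to its resting fixed point (V\* ≈ −1.199).

The document itself is ordinary YAML/JSON:

```r
cat(write_model(m, encoding = "yaml"))
#> fhn_neuron:
#>   format: MDF v0.1
#>   graphs:
#>     main:
#>       nodes:
#>         fhn:
#>           parameters:
#>             ...
#>             V:
#>               default_initial_value: -1.0
#>               time_derivative: V - V**3 / 3 - W + I_ext
#> ...
```

Same pipeline from the shell:

```sh
inst/cli/mdf fixture fhn_neuron fhn.json
inst/cli/mdf validate fhn.json
inst/cli/mdf convert fhn.json fhn.yaml
inst/cli/mdf run fhn.json --dt 0.01 --duration 100 --record fhn/V --output fhn.csv
inst/cli/mdf graph fhn.json --detail full --output fhn.dot
```

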