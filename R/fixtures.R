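# Programmatic model generators used across tests and demos. Fixtures
# are generated, never stored as files, so they cannot drift from the
# schema. Each generator is deterministic given its parameters.

#' Available fixture names
#' @return Character vector.
#' @export
fixture_names <- function() {
  c("ffn_abc", "fhn_neuron", "ddm_accumulator", "condition_demo",
    "cyclic_pair", "nested_model", "tensor_mlp")
}

#' Generate a named fixture model
#'
#' Seven small models spanning the format's expressive range:
#'
#' * `ffn_abc` — stateless 3-node arithmetic chain computing
#'   `((x + 1) * 2) - 3` (7 for the default x = 4) in one pass.
#' * `fhn_neuron` — a FitzHugh-Nagumo neuron as a single node with two
#'   ODE state parameters (`V`, `W`); canonical parameters a = 0.7,
#'   b = 0.8, tau = 12.5, quiescent at `I_ext = 0` (default), oscillating
#'   at `I_ext = 0.5`. Initial state is the `I_ext = 0` fixed point
#'   neighborhood (V = -1, W = -1).
#' * `ddm_accumulator` — drift-diffusion accumulator; `n_paths` > 1
#'   vectorizes the state into that many independent paths sharing one
#'   node (a population-style model).
#' * `condition_demo` — fast/slow two-timescale pair: `slow` runs every
#'   second call of `fast`; both are self-incrementing counters.
#' * `cyclic_pair` — two mutually connected nodes (a legal cycle), both
#'   feeding ports carrying `default_initial_value` 0.
#' * `nested_model` — a subgraph node between a source and a sink;
#'   computes `((x + 10) * 3) - 1` (35 for the default x = 2).
#' * `tensor_mlp` — a 1-layer perceptron `relu(x W + b)` imported from
#'   the tensor-graph dialect.
#'
#' @param name One of [fixture_names()].
#' @param ... Generator parameters (see details above; e.g. `I_ext` for
#'   `fhn_neuron`, `drift_rate`, `noise_coeff`, `n_paths` for
#'   `ddm_accumulator`, `x` for the arithmetic chains).
#' @return An `mdf_model` that passes [validate_model()] with no errors.
#' @examples
#' m <- make_fixture("ffn_abc")
#' run_model(m, max_passes = 1)$final_values$C$out
#' @export
make_fixture <- function(name, ...) {
  params <- list(...)
  switch(name,
    ffn_abc = fixture_ffn_abc(params),
    fhn_neuron = fixture_fhn_neuron(params),
    ddm_accumulator = fixture_ddm(params),
    condition_demo = fixture_condition_demo(params),
    cyclic_pair = fixture_cyclic_pair(params),
    nested_model = fixture_nested(params),
    tensor_mlp = fixture_tensor_mlp(params),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  )
}

fixture_ffn_abc <- function(params) {
  x <- params$x %||% 4
  mdf_model("ffn_abc", graphs = list(mdf_graph("main",
    nodes = list(
      mdf_node("A",
        parameters = list(mdf_parameter("x", value = x)),
        output_ports = list(mdf_output_port("out", "x + 1"))),
      mdf_node("B",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "in1 * 2"))),
      mdf_node("C",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "in1 - 3")))),
    edges = list(
      mdf_edge("ab", "A", "out", "B", "in1"),
      mdf_edge("bc", "B", "out", "C", "in1")))))
}

fixture_fhn_neuron <- function(params) {
  a <- params$a %||% 0.7
  b <- params$b %||% 0.8
  tau <- params$tau %||% 12.5
  I_ext <- params$I_ext %||% 0
  V0 <- params$V0 %||% -1
  W0 <- params$W0 %||% -1
  mdf_model("fhn_neuron", graphs = list(mdf_graph("main",
    nodes = list(mdf_node("fhn",
      parameters = list(
        mdf_parameter("a", value = a),
        mdf_parameter("b", value = b),
        mdf_parameter("tau", value = tau),
        mdf_parameter("I_ext", value = I_ext),
        mdf_parameter("V", default_initial_value = V0,
                      time_derivative = "V - V**3 / 3 - W + I_ext"),
        mdf_parameter("W", default_initial_value = W0,
                      time_derivative = "(V + a - b * W) / tau")),
      output_ports = list(mdf_output_port("V_out", "V")))))))
}

fixture_ddm <- function(params) {
  drift <- params$drift_rate %||% 0.5
  noise <- params$noise_coeff %||% 1
  n_paths <- params$n_paths %||% 1
  x0 <- if (n_paths > 1) rep(0, n_paths) else 0
  mdf_model("ddm_accumulator", graphs = list(mdf_graph("main",
    nodes = list(mdf_node("ddm",
      parameters = list(
        mdf_parameter("drift_rate", value = drift),
        mdf_parameter("noise_coeff", value = noise),
        mdf_parameter("x", default_initial_value = x0,
                      value = "drift_diffusion_step(x, drift_rate, noise_coeff, dt, noise)")),
      functions = list(
        mdf_function_call("noise", "random_standard_normal",
                          args = list(n = n_paths))),
      output_ports = list(mdf_output_port("x_out", "x")))))))
}

fixture_condition_demo <- function(params) {
  n <- as.integer(params$n %||% 2)
  stop_after <- as.integer(params$stop_after %||% 10)
  mdf_model("condition_demo", graphs = list(mdf_graph("main",
    nodes = list(
      mdf_node("fast",
        parameters = list(mdf_parameter("count", value = "count + 1",
                                        default_initial_value = 0)),
        output_ports = list(mdf_output_port("out", "count"))),
      mdf_node("slow",
        parameters = list(mdf_parameter("count", value = "count + 1",
                                        default_initial_value = 0)),
        output_ports = list(mdf_output_port("out", "count")))),
    conditions = mdf_condition_set(
      node_specific = list(slow = cond_every_n_calls("fast", n)),
      termination = cond_after_n_calls("fast", stop_after)))))
}

fixture_cyclic_pair <- function(params) {
  mdf_model("cyclic_pair", graphs = list(mdf_graph("main",
    nodes = list(
      mdf_node("A",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "in1 + 1",
                                            default_initial_value = 0))),
      mdf_node("B",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "in1 * 2",
                                            default_initial_value = 0)))),
    edges = list(
      mdf_edge("ab", "A", "out", "B", "in1"),
      mdf_edge("ba", "B", "out", "A", "in1")))))
}

fixture_nested <- function(params) {
  x <- params$x %||% 2
  inner <- mdf_graph("inner",
    nodes = list(
      mdf_node("Q",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("qout", "in1 + 10"))),
      mdf_node("R",
        input_ports = list(mdf_input_port("rin")),
        output_ports = list(mdf_output_port("out", "rin * 3")))),
    edges = list(mdf_edge("qr", "Q", "qout", "R", "rin")))
  mdf_model("nested_model", graphs = list(mdf_graph("main",
    nodes = list(
      mdf_node("src",
        parameters = list(mdf_parameter("x", value = x)),
        output_ports = list(mdf_output_port("out", "x"))),
      mdf_node("wrap",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "out")),
        subgraph = inner),
      mdf_node("sink",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "in1 - 1")))),
    edges = list(
      mdf_edge("sw", "src", "out", "wrap", "in1"),
      mdf_edge("ws", "wrap", "out", "sink", "in1")))))
}

fixture_tensor_mlp <- function(params) {
  x <- params$x %||% c(1, 2)
  W <- params$W %||% matrix(c(1, -2, 3, 0.5), nrow = 2, byrow = TRUE)
  b <- params$b %||% c(0.5, -1)
  doc <- tensor_graph(
    inputs = list(
      x = list(shape = length(x), value = x),
      W = list(shape = dim(W), value = W),
      b = list(shape = length(b), value = b)),
    ops = list(
      list(op = "matmul", inputs = c("x", "W"), output = "h",
           attributes = list()),
      list(op = "add", inputs = c("h", "b"), output = "s",
           attributes = list()),
      list(op = "relu", inputs = c("s"), output = "y",
           attributes = list())),
    outputs = "y")
  import_tensor_graph(doc, model_id = "tensor_mlp")
}
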