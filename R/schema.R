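# Document object model: Model / Graph / Node / ports / Parameter /
# FunctionCall / Edge. Objects are plain lists with S3 classes;
# validate_model() performs the full invariant pass so constructors only
# check argument types.
#
# Identifier grammar: [A-Za-z_][A-Za-z0-9_]*. Dots are reserved for
# hierarchy namespacing, so node ids in a flattened model may be
# dot-joined chains of identifiers; port/parameter/function ids never
# contain dots.

ID_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"
NODE_ID_RE <- "^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z_][A-Za-z0-9_]*)*$"

is_id <- function(x) is.character(x) && length(x) == 1L && grepl(ID_RE, x)
is_node_id <- function(x) is.character(x) && length(x) == 1L &&
  grepl(NODE_ID_RE, x)

# identifiers implicitly bound by the engine inside every node
BUILTIN_IDS <- c("dt", "time")

#' Construct a model
#'
#' The top-level document: an ordered list of graphs plus format/version
#' metadata.
#'
#' @param id Identifier string.
#' @param graphs List of [mdf_graph()] objects.
#' @param format_version Format version string.
#' @param metadata Named list of scalar metadata.
#' @return An object of class `mdf_model`.
#' @export
mdf_model <- function(id, graphs = list(), format_version = "MDF v0.1",
                      metadata = list()) {
  structure(list(id = id, format_version = format_version,
                 graphs = graphs, metadata = metadata),
            class = "mdf_model")
}

#' Construct a graph
#'
#' @param id Identifier string.
#' @param nodes List of [mdf_node()] objects (declaration order matters
#'   for scheduling tie-breaks).
#' @param edges List of [mdf_edge()] objects.
#' @param conditions Optional [mdf_condition_set()].
#' @param metadata Named list.
#' @return An object of class `mdf_graph`.
#' @export
mdf_graph <- function(id, nodes = list(), edges = list(),
                      conditions = NULL, metadata = list()) {
  structure(list(id = id, nodes = nodes, edges = edges,
                 conditions = conditions, metadata = metadata),
            class = "mdf_graph")
}

#' Construct a node
#'
#' A computational unit bundling input ports, parameters, function calls
#' and output ports — or, for hierarchical composition, a subgraph
#' (mutually exclusive with parameters/functions). A subgraph node's
#' input/output ports map one-to-one by id onto like-named ports of the
#' inner graph's nodes.
#'
#' @param id Identifier string.
#' @param input_ports,parameters,functions,output_ports Lists of the
#'   respective component objects.
#' @param subgraph Optional [mdf_graph()] for hierarchical composition.
#' @param metadata Named list.
#' @return An object of class `mdf_node`.
#' @export
mdf_node <- function(id, input_ports = list(), parameters = list(),
                     functions = list(), output_ports = list(),
                     subgraph = NULL, metadata = list()) {
  structure(list(id = id, input_ports = input_ports,
                 parameters = parameters, functions = functions,
                 output_ports = output_ports, subgraph = subgraph,
                 metadata = metadata),
            class = "mdf_node")
}

#' Construct an input port
#'
#' @param id Identifier string.
#' @param shape Optional integer vector of positive extents.
#' @param reduce How to combine multiple incoming edges: `"error"`
#'   (default — fan-in must be declared) or `"sum"`.
#' @return An object of class `mdf_input_port`.
#' @export
mdf_input_port <- function(id, shape = NULL, reduce = c("error", "sum")) {
  reduce <- match.arg(reduce)
  structure(list(id = id, shape = shape, reduce = reduce),
            class = "mdf_input_port")
}

#' Construct an output port
#'
#' @param id Identifier string.
#' @param value Expression string over node-local ids.
#' @param default_initial_value Optional numeric/array used before the
#'   node first executes; required when the port feeds a cycle.
#' @return An object of class `mdf_output_port`.
#' @export
mdf_output_port <- function(id, value, default_initial_value = NULL) {
  structure(list(id = id, value = value,
                 default_initial_value = default_initial_value),
            class = "mdf_output_port")
}

#' Construct a parameter
#'
#' A parameter is *stateful* when it has a `time_derivative` (an ODE
#' state variable advanced by the engine's integrator) or when its value
#' expression references its own id (a cross-execution accumulator).
#' Stateful parameters require a `default_initial_value`.
#'
#' @param id Identifier string.
#' @param value Numeric constant or expression string.
#' @param default_initial_value Optional numeric/array.
#' @param time_derivative Optional expression string for dv/dt.
#' @return An object of class `mdf_parameter`.
#' @export
mdf_parameter <- function(id, value = NULL, default_initial_value = NULL,
                          time_derivative = NULL) {
  structure(list(id = id, value = value,
                 default_initial_value = default_initial_value,
                 time_derivative = time_derivative),
            class = "mdf_parameter")
}

param_is_stateful <- function(p) {
  if (!is.null(p$time_derivative)) return(TRUE)
  if (is.character(p$value)) {
    ids <- tryCatch(free_identifiers(p$value), error = function(e) character(0))
    return(p$id %in% ids)
  }
  FALSE
}

#' Construct a function call
#'
#' @param id Identifier string (the slot name the result binds to).
#' @param function_name Name resolving in the function ontology.
#' @param args Named list mapping the function's parameter names to
#'   expression strings or numeric constants.
#' @return An object of class `mdf_function_call`.
#' @export
mdf_function_call <- function(id, function_name, args = list()) {
  structure(list(id = id, "function" = function_name, args = args),
            class = "mdf_function_call")
}

#' Construct an edge
#'
#' A directed data link from an output port to an input port on another
#' (or the same) node.
#'
#' @param id Identifier string.
#' @param sender,sender_port Source node and output-port ids.
#' @param receiver,receiver_port Destination node and input-port ids.
#' @param weight Optional scalar multiplier applied in transit
#'   (default 1).
#' @return An object of class `mdf_edge`.
#' @export
mdf_edge <- function(id, sender, sender_port, receiver, receiver_port,
                     weight = NULL) {
  structure(list(id = id, sender = sender, sender_port = sender_port,
                 receiver = receiver, receiver_port = receiver_port,
                 weight = weight),
            class = "mdf_edge")
}

#' @export
print.mdf_model <- function(x, ...) {
  cat(sprintf("<mdf model '%s'> (%s), %d graph(s)\n", x$id,
              x$format_version, length(x$graphs)))
  for (g in x$graphs) {
    cat(sprintf("  graph '%s': %d node(s), %d edge(s)%s\n", g$id,
                length(g$nodes), length(g$edges),
                if (is.null(g$conditions)) "" else ", conditioned"))
  }
  invisible(x)
}

component_ids <- function(items) vapply(items, `[[`, "", "id")

node_slot_ids <- function(node) {
  c(component_ids(node$parameters), component_ids(node$functions))
}

node_local_ids <- function(node) {
  c(component_ids(node$input_ports), node_slot_ids(node))
}

find_by_id <- function(items, id) {
  for (it in items) if (identical(it$id, id)) return(it)
  NULL
}
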