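# Structural visualization (Graphviz DOT export) and a minimal
# bidirectional bridge to a flat tensor-graph dialect that uses the core
# operator names and semantics. The bridge demonstrates hub-and-spoke
# translation on the exportable fragment: acyclic, always-conditions,
# stateless, core-set functions only. Export fails loudly outside the
# fragment — silent semantic drift is the failure mode a standardized
# format exists to prevent.

dot_quote <- function(s) paste0("\"", gsub("([\"\\\\])", "\\\\\\1", s), "\"")

dot_escape_label <- function(s) {
  gsub("([<>{}|\"\\\\])", "\\\\\\1", s)
}

#' Export a model's structure as Graphviz DOT text
#'
#' Deterministic output (components sorted by id): re-exporting the same
#' model yields identical text.
#'
#' @param model An `mdf_model`.
#' @param detail `"nodes_only"` (one DOT node per graph node, one DOT
#'   edge per edge) or `"full"` (record-shaped nodes listing ports,
#'   parameters and functions).
#' @param graph_id Graph to draw (default: first).
#' @return DOT source as a single character string.
#' @export
to_dot <- function(model, detail = c("nodes_only", "full"),
                   graph_id = NULL) {
  detail <- match.arg(detail)
  g <- if (is.null(graph_id)) model$graphs[[1]]
       else find_by_id(model$graphs, graph_id)
  lines <- c(paste0("digraph ", dot_quote(model$id), " {"),
             "  rankdir=LR;")
  if (!is.null(g)) {
    ids <- sort(component_ids(g$nodes), method = "radix")
    for (nid in ids) {
      nd <- find_by_id(g$nodes, nid)
      if (detail == "nodes_only") {
        lines <- c(lines, paste0("  ", dot_quote(nid), ";"))
      } else {
        seg <- function(items, fmt) {
          if (length(items) == 0L) return(NULL)
          paste(vapply(items, fmt, ""), collapse = "\\n")
        }
        parts <- c(
          dot_escape_label(nid),
          seg(nd$input_ports, function(p)
            paste0("in: ", dot_escape_label(p$id))),
          seg(nd$parameters, function(p)
            dot_escape_label(paste0(p$id, if (is.character(p$value))
              paste0(" = ", p$value)
              else if (is.numeric(p$value) && length(p$value) == 1L)
                paste0(" = ", format(p$value)) else ""))),
          seg(nd$functions, function(f)
            dot_escape_label(paste0(f$id, " = ", f[["function"]], "(...)"))),
          seg(nd$output_ports, function(p)
            dot_escape_label(paste0("out ", p$id, " = ", p$value)))
        )
        label <- paste0("{", paste(parts[!vapply(parts, is.null,
                                                 logical(1))],
                                   collapse = "|"), "}")
        lines <- c(lines, paste0("  ", dot_quote(nid),
                                 " [shape=record, label=",
                                 dot_quote(label), "];"))
      }
    }
    ek <- vapply(g$edges, function(e)
      paste(e$sender, e$sender_port, e$receiver, e$receiver_port,
            sep = "\r"), "")
    for (e in g$edges[order(ek, method = "radix")]) {
      attr_txt <- if (detail == "full" || (!is.null(e$weight) &&
                                           e$weight != 1)) {
        lbl <- paste0(e$sender_port, " > ", e$receiver_port,
                      if (!is.null(e$weight) && e$weight != 1)
                        paste0(" (w=", format(e$weight), ")") else "")
        paste0(" [label=", dot_quote(lbl), "]")
      } else ""
      lines <- c(lines, paste0("  ", dot_quote(e$sender), " -> ",
                               dot_quote(e$receiver), attr_txt, ";"))
    }
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

# ---- tensor-graph dialect -------------------------------------------------

#' Construct a tensor-graph document
#'
#' A flat single-assignment tensor dialect using the core operator names
#' and semantics: named graph inputs, an ordered op list (each consuming
#' previously defined value names and producing one new name), and the
#' graph output names.
#'
#' @param inputs Named list: input name -> list with optional `shape`
#'   and optional `value` (default input data).
#' @param ops List of op entries: `list(op =, inputs = c(...), output =,
#'   attributes = list(...))`.
#' @param outputs Character vector of produced value names.
#' @return An object of class `mdf_tensor_graph`.
#' @export
tensor_graph <- function(inputs = list(), ops = list(),
                         outputs = character(0)) {
  structure(list(inputs = inputs, ops = ops, outputs = outputs),
            class = "mdf_tensor_graph")
}

validate_tensor_graph <- function(doc, registry = core_operator_set()) {
  defined <- names(doc$inputs) %||% character(0)
  core <- setdiff(registry_names(registry),
                  c("fitzhugh_nagumo_dV", "fitzhugh_nagumo_dW",
                    "drift_diffusion_step", "random_standard_normal"))
  for (op in doc$ops) {
    if (!(op$op %in% core))
      stop(sprintf("unknown op name '%s'", op$op), call. = FALSE)
    for (i in op$inputs)
      if (!(i %in% defined))
        stop(sprintf("op '%s' consumes undefined value '%s'",
                     op$output, i), call. = FALSE)
    if (op$output %in% defined)
      stop(sprintf("multiple assignment of value '%s'", op$output),
           call. = FALSE)
    defined <- c(defined, op$output)
  }
  for (o in doc$outputs)
    if (!(o %in% defined))
      stop(sprintf("graph output '%s' is never produced", o),
           call. = FALSE)
  invisible(TRUE)
}

#' Read / write a tensor-graph document (JSON)
#'
#' @param path File path.
#' @return `read_tensor_graph`: an `mdf_tensor_graph`;
#'   `write_tensor_graph`: the path, invisibly.
#' @export
read_tensor_graph <- function(path) {
  t <- jsonlite::parse_json(
    readChar(path, file.info(path)$size, useBytes = TRUE))
  inputs <- lapply(t$inputs %||% list(), function(i) {
    list(shape = if (!is.null(i$shape)) as.integer(unlist(i$shape))
         else NULL,
         value = if (!is.null(i$value)) tree_to_value(i$value) else NULL)
  })
  ops <- lapply(t$ops %||% list(), function(o)
    list(op = o$op, inputs = as.character(unlist(o$inputs)),
         output = o$output,
         attributes = lapply(o$attributes %||% list(), function(a)
           if (is.character(a)) a else tree_to_value(a))))
  tensor_graph(inputs, ops, as.character(unlist(t$outputs %||% list())))
}

#' @rdname read_tensor_graph
#' @param doc An `mdf_tensor_graph`.
#' @export
write_tensor_graph <- function(doc, path) {
  t <- list(
    inputs = if (length(doc$inputs)) lapply(doc$inputs, function(i)
      compact(list(
        shape = if (!is.null(i$shape)) as.list(as.integer(i$shape))
                else NULL,
        value = if (!is.null(i$value)) value_to_tree(i$value) else NULL)))
      else empty_map(),
    ops = lapply(doc$ops, function(o) compact(list(
      op = o$op, inputs = as.list(o$inputs), output = o$output,
      attributes = if (length(o$attributes))
        lapply(o$attributes, function(a)
          if (is.character(a)) a else value_to_tree(a)) else NULL))),
    outputs = as.list(doc$outputs))
  writeChar(paste0(jsonlite::toJSON(t, auto_unbox = TRUE, digits = NA,
                                    pretty = 2, null = "null"), "\n"),
            path, eos = NULL)
  invisible(path)
}

#' Import a tensor-graph document as a model
#'
#' Each op becomes a node carrying one function call; value names become
#' edges; graph inputs become parameter-fed source nodes whose `value`
#' parameter holds the input data (settable with [set_input_value()]).
#' The result passes validation.
#'
#' @param doc An `mdf_tensor_graph`.
#' @param model_id Id for the resulting model.
#' @param registry Function registry (core operators).
#' @return An `mdf_model`.
#' @export
import_tensor_graph <- function(doc, model_id = "tensor_model",
                                registry = core_operator_set()) {
  validate_tensor_graph(doc, registry)
  nodes <- list()
  edges <- list()
  producer <- list()  # value name -> node id
  for (nm in names(doc$inputs)) {
    inp <- doc$inputs[[nm]]
    v <- inp$value %||% 0
    nodes[[length(nodes) + 1L]] <- mdf_node(nm,
      parameters = list(mdf_parameter("value", value = v)),
      output_ports = list(mdf_output_port("out", "value")))
    producer[[nm]] <- nm
  }
  for (op in doc$ops) {
    def <- lookup_function(registry, op$op)
    spec_names <- vapply(def$args, `[[`, "", "name")
    ports <- list()
    args <- list()
    for (i in seq_along(op$inputs)) {
      pid <- paste0("in", i)
      ports[[i]] <- mdf_input_port(pid)
      args[[spec_names[i]]] <- pid
    }
    for (an in names(op$attributes %||% list()))
      args[[an]] <- op$attributes[[an]]
    nodes[[length(nodes) + 1L]] <- mdf_node(op$output,
      input_ports = ports,
      functions = list(mdf_function_call("f", op$op, args)),
      output_ports = list(mdf_output_port("out", "f")))
    for (i in seq_along(op$inputs)) {
      src <- op$inputs[i]
      edges[[length(edges) + 1L]] <- mdf_edge(
        paste0("e_", src, "_", op$output, "_", i),
        sender = producer[[src]], sender_port = "out",
        receiver = op$output, receiver_port = paste0("in", i))
    }
    producer[[op$output]] <- op$output
  }
  g <- mdf_graph("main", nodes = nodes, edges = edges)
  mdf_model(model_id, graphs = list(g),
            metadata = list(outputs = paste(doc$outputs, collapse = ",")))
}

#' Set the value of an imported graph input
#'
#' @param model A model produced by [import_tensor_graph()].
#' @param name Input (node) name.
#' @param value Numeric scalar or array.
#' @return The modified model.
#' @export
set_input_value <- function(model, name, value) {
  for (gi in seq_along(model$graphs)) {
    g <- model$graphs[[gi]]
    for (ni in seq_along(g$nodes)) {
      if (identical(g$nodes[[ni]]$id, name)) {
        for (pi in seq_along(g$nodes[[ni]]$parameters)) {
          if (identical(g$nodes[[ni]]$parameters[[pi]]$id, "value")) {
            model$graphs[[gi]]$nodes[[ni]]$parameters[[pi]]$value <- value
            return(model)
          }
        }
      }
    }
  }
  stop(sprintf("no input node '%s'", name), call. = FALSE)
}

#' Export a model to the tensor-graph dialect
#'
#' Defined on the exportable fragment: acyclic graph, always-conditions,
#' no stateful parameters or time derivatives, every computing node a
#' single core-set function call. Constructs outside the fragment raise
#' an error naming the construct and node.
#'
#' @param model An `mdf_model`.
#' @param graph_id Graph to export (default: first).
#' @param registry Function registry.
#' @return An `mdf_tensor_graph`.
#' @export
export_tensor_graph <- function(model, graph_id = NULL,
                                registry = core_operator_set()) {
  model <- flatten_hierarchy(model)
  g <- if (is.null(graph_id)) model$graphs[[1]]
       else find_by_id(model$graphs, graph_id)
  cyc <- detect_cycles(g)
  if (length(cyc) > 0L)
    stop(sprintf("not exportable: cycle through node '%s'", cyc[[1]][1]),
         call. = FALSE)
  if (!is.null(g$conditions)) {
    for (nm in names(g$conditions$node_specific)) {
      c <- g$conditions$node_specific[[nm]]
      if (!identical(c$type, "always"))
        stop(sprintf("not exportable: condition '%s' on node '%s'",
                     condition_describe(c), nm), call. = FALSE)
    }
  }
  core <- setdiff(registry_names(registry),
                  c("fitzhugh_nagumo_dV", "fitzhugh_nagumo_dW",
                    "drift_diffusion_step", "random_standard_normal"))
  inputs <- list()
  ops <- list()
  produced_by_node <- list()
  # topological order over edges (graph is acyclic)
  order <- next_execution_set(g, NULL, scheduler_state(g))
  has_incoming <- unique(vapply(g$edges, `[[`, "", "receiver"))
  for (nid in order) {
    nd <- find_by_id(g$nodes, nid)
    for (p in nd$parameters) {
      if (param_is_stateful(p))
        stop(sprintf("not exportable: stateful parameter '%s' on node '%s'",
                     p$id, nid), call. = FALSE)
    }
    if (!(nid %in% has_incoming) && length(nd$functions) == 0L &&
        length(nd$parameters) == 1L && length(nd$output_ports) == 1L &&
        identical(nd$output_ports[[1]]$value, nd$parameters[[1]]$id)) {
      v <- nd$parameters[[1]]$value
      inputs[[nid]] <- list(shape = if (is.numeric(v)) value_shape(v)
                            else NULL,
                            value = if (is.numeric(v)) v else NULL)
      produced_by_node[[nid]] <- nid
      next
    }
    if (length(nd$functions) != 1L)
      stop(sprintf("not exportable: node '%s' is not a single function call",
                   nid), call. = FALSE)
    f <- nd$functions[[1]]
    if (!(f[["function"]] %in% core))
      stop(sprintf("not exportable: function '%s' on node '%s' is outside the core operator set",
                   f[["function"]], nid), call. = FALSE)
    if (length(nd$output_ports) != 1L ||
        !identical(nd$output_ports[[1]]$value, f$id))
      stop(sprintf("not exportable: node '%s' output is not the function result",
                   nid), call. = FALSE)
    def <- lookup_function(registry, f[["function"]])
    spec_names <- vapply(def$args, `[[`, "", "name")
    # map port-valued args (in positional spec order) to producing values
    op_inputs <- character(0)
    attributes <- list()
    port_ids <- component_ids(nd$input_ports)
    for (an in spec_names) {
      a <- f$args[[an]]
      if (is.null(a)) next
      if (is.character(a) && a %in% port_ids) {
        feeding <- Filter(function(e)
          identical(e$receiver, nid) && identical(e$receiver_port, a),
          g$edges)
        if (length(feeding) != 1L)
          stop(sprintf("not exportable: port '%s.%s' needs exactly one incoming edge",
                       nid, a), call. = FALSE)
        if (!is.null(feeding[[1]]$weight) && feeding[[1]]$weight != 1)
          stop(sprintf("not exportable: weighted edge '%s'",
                       feeding[[1]]$id), call. = FALSE)
        op_inputs <- c(op_inputs, produced_by_node[[feeding[[1]]$sender]])
      } else {
        attributes[[an]] <- if (is.character(a))
          evaluate_expression(a, list(), registry) else a
      }
    }
    ops[[length(ops) + 1L]] <- list(op = f[["function"]],
                                    inputs = op_inputs, output = nid,
                                    attributes = attributes)
    produced_by_node[[nid]] <- nid
  }
  has_outgoing <- unique(vapply(g$edges, `[[`, "", "sender"))
  sinks <- setdiff(vapply(ops, `[[`, "", "output"), has_outgoing)
  doc <- tensor_graph(inputs, ops, sinks)
  validate_tensor_graph(doc, registry)
  doc
}
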