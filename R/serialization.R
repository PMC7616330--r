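# Reading and writing model documents in JSON, YAML and binary
# (MessagePack) encodings. All three encodings carry the identical
# document tree:
#
#   {"<model_id>": {"format": ..., "graphs": {...}, "metadata": {...}}}
#
# Collections (graphs, nodes, edges, ports, parameters, functions)
# serialize as maps keyed by id; declaration order is recovered from key
# order. Writing is deterministic — keys in schema-defined order, floats
# at full round-trip precision — so writing the same model twice yields
# byte-identical payloads, and write(read(write(m))) is byte-identical
# to write(m). NaN/Infinity are encoded as the strings "NaN"/"Infinity"/
# "-Infinity" in JSON (which lacks them) and natively in YAML/binary.

SCHEMA_VERSION <- "MDF v0.1"

# ---- neutral tree construction -------------------------------------------
# scalars: length-1 atomic; arrays: (nested) unnamed lists of scalars;
# maps: named lists (empty maps keep names = character(0))

empty_map <- function() structure(list(), names = character(0))

value_to_tree <- function(v) {
  if (is.null(dim(v)) && length(v) == 1L) return(as.numeric(v))
  if (is.null(dim(v))) return(as.list(as.numeric(v)))
  d <- dim(v)
  if (length(d) == 2L)
    return(lapply(seq_len(d[1]), function(i) as.list(as.numeric(v[i, ]))))
  lapply(seq_len(d[1]), function(i)
    value_to_tree(array(v[slice.index(v, 1L) == i], dim = d[-1])))
}

tree_to_value <- function(t, where = "value") {
  if (is.numeric(t) && length(t) == 1L) return(as.numeric(t))
  if (!is.list(t))
    stop(sprintf("%s: expected a number or array", where), call. = FALSE)
  if (length(t) == 0L) return(numeric(0))
  if (is.list(t[[1]])) {
    rows <- lapply(seq_along(t), function(i)
      tree_to_value(t[[i]], where))
    mat <- do.call(rbind, rows)
    return(mat)
  }
  as.numeric(unlist(t))
}

expr_or_value_to_tree <- function(v) {
  if (is.character(v)) v else value_to_tree(v)
}

compact <- function(x) x[!vapply(x, is.null, logical(1))]

meta_tree <- function(md) {
  if (is.null(md) || length(md) == 0L) return(NULL)
  md
}

model_to_tree <- function(model) {
  body <- compact(list(
    format = model$format_version,
    graphs = {
      g <- lapply(model$graphs, graph_to_tree)
      names(g) <- component_ids(model$graphs)
      if (length(g) == 0L) empty_map() else g
    },
    metadata = meta_tree(model$metadata)
  ))
  out <- list()
  out[[model$id]] <- body
  out
}

graph_to_tree <- function(g) {
  nodes <- lapply(g$nodes, node_to_tree)
  names(nodes) <- component_ids(g$nodes)
  edges <- lapply(g$edges, edge_to_tree)
  names(edges) <- component_ids(g$edges)
  compact(list(
    nodes = if (length(nodes)) nodes else empty_map(),
    edges = if (length(edges)) edges else empty_map(),
    conditions = if (!is.null(g$conditions))
      condition_set_to_tree(g$conditions) else NULL,
    metadata = meta_tree(g$metadata)
  ))
}

node_to_tree <- function(nd) {
  named_or_null <- function(items, f) {
    if (length(items) == 0L) return(NULL)
    out <- lapply(items, f)
    names(out) <- component_ids(items)
    out
  }
  compact(list(
    input_ports = named_or_null(nd$input_ports, function(p) compact(list(
      shape = if (!is.null(p$shape)) as.list(as.integer(p$shape)) else NULL,
      reduce = if (!identical(p$reduce, "error")) p$reduce else NULL
    ))),
    parameters = named_or_null(nd$parameters, function(p) compact(list(
      value = if (!is.null(p$value)) expr_or_value_to_tree(p$value) else NULL,
      default_initial_value = if (!is.null(p$default_initial_value))
        value_to_tree(p$default_initial_value) else NULL,
      time_derivative = p$time_derivative
    ))),
    functions = named_or_null(nd$functions, function(f) compact(list(
      "function" = f[["function"]],
      args = if (length(f$args))
        lapply(f$args, expr_or_value_to_tree) else NULL
    ))),
    output_ports = named_or_null(nd$output_ports, function(p) compact(list(
      value = p$value,
      default_initial_value = if (!is.null(p$default_initial_value))
        value_to_tree(p$default_initial_value) else NULL
    ))),
    subgraph = if (!is.null(nd$subgraph)) {
      sg <- list()
      sg[[nd$subgraph$id]] <- graph_to_tree(nd$subgraph)
      sg
    } else NULL,
    metadata = meta_tree(nd$metadata)
  ))
}

edge_to_tree <- function(e) {
  compact(list(
    sender = e$sender, sender_port = e$sender_port,
    receiver = e$receiver, receiver_port = e$receiver_port,
    weight = if (!is.null(e$weight) && e$weight != 1)
      as.numeric(e$weight) else NULL
  ))
}

condition_to_tree <- function(c) {
  args <- switch(c$type,
    every_n_calls = ,
    after_n_calls = ,
    before_n_calls = list(dep_node = c$dep_node, n = as.numeric(c$n)),
    threshold = list(node = c$node, parameter = c$parameter,
                     comparator = c$comparator, value = c$value),
    time_interval = list(start = c$start, end = c$end),
    and = ,
    or = list(terms = lapply(c$terms, condition_to_tree)),
    not = list(inner = condition_to_tree(c$inner)),
    empty_map()
  )
  list(type = c$type, args = args)
}

condition_set_to_tree <- function(cs) {
  compact(list(
    node_specific = if (length(cs$node_specific))
      lapply(cs$node_specific, condition_to_tree) else NULL,
    termination = if (!is.null(cs$termination))
      condition_to_tree(cs$termination) else NULL
  ))
}

# ---- tree -> model --------------------------------------------------------

new_warn_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$msgs <- character(0)
  env
}

note_warn <- function(wc, msg) {
  wc$msgs <- c(wc$msgs, msg)
  warning(msg, call. = FALSE)
}

known_keys <- function(tree, known, wc, where) {
  unknown <- setdiff(names(tree), known)
  meta <- tree$metadata %||% list()
  for (k in unknown) {
    note_warn(wc, sprintf("%s: unknown key '%s' preserved in metadata",
                          where, k))
    meta[[k]] <- tree[[k]]
  }
  meta
}

expect_map <- function(x, where) {
  if (is.null(x)) return(empty_map())
  if (!is.list(x) || (length(x) > 0L && is.null(names(x))))
    stop(sprintf("schema violation at %s: expected a map", where),
         call. = FALSE)
  x
}

expect_string <- function(x, where) {
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("schema violation at %s: expected a string", where),
         call. = FALSE)
  x
}

tree_to_model <- function(tree, wc = new_warn_collector()) {
  tree <- expect_map(tree, "document root")
  if (length(tree) != 1L)
    stop("schema violation: document must hold exactly one model entry",
         call. = FALSE)
  mid <- names(tree)
  body <- expect_map(tree[[1]], mid)
  fmt <- body$format %||% SCHEMA_VERSION
  if (!is.character(fmt))
    stop("schema violation: 'format' must be a string", call. = FALSE)
  if (!grepl("^MDF v0\\.", fmt))
    stop(sprintf("unsupported schema_version '%s'", fmt), call. = FALSE)
  graphs_tree <- expect_map(body$graphs, paste0(mid, ".graphs"))
  graphs <- lapply(names(graphs_tree), function(gid)
    tree_to_graph(gid, graphs_tree[[gid]], wc, paste0("graph ", gid)))
  meta <- known_keys(body, c("format", "graphs", "metadata"), wc, mid)
  mdf_model(mid, graphs = graphs, format_version = fmt,
            metadata = meta)
}

tree_to_graph <- function(gid, t, wc, where) {
  t <- expect_map(t, where)
  nodes_tree <- expect_map(t$nodes, paste0(where, ".nodes"))
  nodes <- lapply(names(nodes_tree), function(nid)
    tree_to_node(nid, nodes_tree[[nid]], wc,
                 paste0(where, " node ", nid)))
  edges_tree <- expect_map(t$edges, paste0(where, ".edges"))
  edges <- lapply(names(edges_tree), function(eid) {
    et <- expect_map(edges_tree[[eid]], paste0(where, " edge ", eid))
    mdf_edge(eid,
             sender = expect_string(et$sender %||% "",
                                    paste0(where, " edge ", eid)),
             sender_port = expect_string(et$sender_port %||% "",
                                         paste0(where, " edge ", eid)),
             receiver = expect_string(et$receiver %||% "",
                                      paste0(where, " edge ", eid)),
             receiver_port = expect_string(et$receiver_port %||% "",
                                           paste0(where, " edge ", eid)),
             weight = if (!is.null(et$weight)) as.numeric(et$weight)
                      else NULL)
  })
  conditions <- if (!is.null(t$conditions))
    tree_to_condition_set(t$conditions, paste0(where, ".conditions"))
  else NULL
  meta <- known_keys(t, c("nodes", "edges", "conditions", "metadata"),
                     wc, where)
  mdf_graph(gid, nodes = nodes, edges = edges, conditions = conditions,
            metadata = meta)
}

tree_to_node <- function(nid, t, wc, where) {
  t <- expect_map(t, where)
  ip_tree <- expect_map(t$input_ports, paste0(where, ".input_ports"))
  input_ports <- lapply(names(ip_tree), function(pid) {
    pt <- expect_map(ip_tree[[pid]], paste0(where, " port ", pid))
    mdf_input_port(pid,
                   shape = if (!is.null(pt$shape))
                     as.integer(unlist(pt$shape)) else NULL,
                   reduce = if (!is.null(pt$reduce)) pt$reduce else "error")
  })
  par_tree <- expect_map(t$parameters, paste0(where, ".parameters"))
  parameters <- lapply(names(par_tree), function(pid) {
    pt <- expect_map(par_tree[[pid]], paste0(where, " parameter ", pid))
    mdf_parameter(pid,
                  value = if (is.null(pt$value)) NULL
                          else if (is.character(pt$value)) pt$value
                          else tree_to_value(pt$value, paste0(pid, ".value")),
                  default_initial_value = if (!is.null(pt$default_initial_value))
                    tree_to_value(pt$default_initial_value,
                                  paste0(pid, ".default_initial_value"))
                  else NULL,
                  time_derivative = pt$time_derivative)
  })
  fn_tree <- expect_map(t$functions, paste0(where, ".functions"))
  functions <- lapply(names(fn_tree), function(fid) {
    ft <- expect_map(fn_tree[[fid]], paste0(where, " function ", fid))
    args <- lapply(expect_map(ft$args, paste0(fid, ".args")), function(a)
      if (is.character(a)) a else tree_to_value(a, paste0(fid, ".args")))
    mdf_function_call(fid,
                      function_name = expect_string(ft[["function"]] %||% "",
                                                    paste0(fid, ".function")),
                      args = args)
  })
  op_tree <- expect_map(t$output_ports, paste0(where, ".output_ports"))
  output_ports <- lapply(names(op_tree), function(pid) {
    pt <- expect_map(op_tree[[pid]], paste0(where, " port ", pid))
    mdf_output_port(pid,
                    value = pt$value,
                    default_initial_value = if (!is.null(pt$default_initial_value))
                      tree_to_value(pt$default_initial_value,
                                    paste0(pid, ".default_initial_value"))
                    else NULL)
  })
  subgraph <- NULL
  if (!is.null(t$subgraph)) {
    sgt <- expect_map(t$subgraph, paste0(where, ".subgraph"))
    if (length(sgt) != 1L)
      stop(sprintf("schema violation at %s: subgraph must hold one graph",
                   where), call. = FALSE)
    subgraph <- tree_to_graph(names(sgt), sgt[[1]], wc,
                              paste0(where, " subgraph ", names(sgt)))
  }
  meta <- known_keys(t, c("input_ports", "parameters", "functions",
                          "output_ports", "subgraph", "metadata"),
                     wc, where)
  mdf_node(nid, input_ports = input_ports, parameters = parameters,
           functions = functions, output_ports = output_ports,
           subgraph = subgraph, metadata = meta)
}

tree_to_condition_set <- function(t, where) {
  t <- expect_map(t, where)
  ns <- lapply(expect_map(t$node_specific, paste0(where, ".node_specific")),
               tree_to_condition)
  term <- if (!is.null(t$termination)) tree_to_condition(t$termination)
          else cond_all_have_run()
  mdf_condition_set(node_specific = ns, termination = term)
}

tree_to_condition <- function(t) {
  type <- t$type
  a <- t$args %||% list()
  switch(type,
    always = cond_always(),
    never = cond_never(),
    every_n_calls = cond_every_n_calls(a$dep_node, a$n),
    after_n_calls = cond_after_n_calls(a$dep_node, a$n),
    before_n_calls = cond_before_n_calls(a$dep_node, a$n),
    threshold = cond_threshold(a$node, a$parameter, a$comparator, a$value),
    time_interval = cond_time_interval(a$start %||% -Inf, a$end %||% Inf),
    and = do.call(cond_and, lapply(a$terms, tree_to_condition)),
    or = do.call(cond_or, lapply(a$terms, tree_to_condition)),
    not = cond_not(tree_to_condition(a$inner)),
    all_have_run = cond_all_have_run(),
    stop(sprintf("schema violation: unknown condition type '%s'",
                 as.character(type)), call. = FALSE)
  )
}

# ---- encodings ------------------------------------------------------------

# JSON lacks NaN/Infinity: swap them for marker strings (and back)
nonfinite_to_strings <- function(t) {
  if (is.numeric(t) && length(t) == 1L && !is.finite(t)) {
    return(if (is.nan(t)) "NaN" else if (t > 0) "Infinity" else "-Infinity")
  }
  if (is.list(t)) {
    for (i in seq_along(t)) t[[i]] <- nonfinite_to_strings(t[[i]])
  }
  t
}

strings_to_nonfinite <- function(t) {
  if (is.character(t) && length(t) == 1L &&
      t %in% c("NaN", "Infinity", "-Infinity")) {
    return(switch(t, "NaN" = NaN, "Infinity" = Inf, "-Infinity" = -Inf))
  }
  if (is.list(t)) {
    for (i in seq_along(t)) t[[i]] <- strings_to_nonfinite(t[[i]])
  }
  t
}

tree_to_json <- function(tree) {
  tree <- nonfinite_to_strings(tree)
  # digits = I(17): significant digits, enough for bit-exact doubles
  paste0(jsonlite::toJSON(tree, auto_unbox = TRUE, digits = I(17),
                          pretty = 2, null = "null"), "\n")
}

json_to_tree <- function(txt) {
  tree <- tryCatch(
    jsonlite::parse_json(txt),
    error = function(e)
      stop(sprintf("JSON syntax error: %s", conditionMessage(e)),
           call. = FALSE))
  strings_to_nonfinite(tree)
}

tree_to_yaml <- function(tree) {
  yaml::as.yaml(tree, precision = 17L, indent.mapping.sequence = TRUE)
}

yaml_to_tree <- function(txt) {
  tryCatch(
    yaml::yaml.load(txt, handlers = list(seq = function(x) as.list(x))),
    error = function(e)
      stop(sprintf("YAML syntax error: %s", conditionMessage(e)),
           call. = FALSE))
}

encoding_of_path <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.json$", lower)) "json"
  else if (grepl("\\.ya?ml$", lower)) "yaml"
  else if (grepl("\\.bin$", lower)) "binary"
  else stop(sprintf("cannot infer encoding from '%s' (use .json/.yaml/.bin)",
                    path), call. = FALSE)
}

#' Write a model document
#'
#' Serializes a validated model to JSON, YAML or the binary (MessagePack)
#' encoding. The three encodings carry the identical document tree, and
#' writing is deterministic: the same model always yields byte-identical
#' payloads. An invalid model is refused with the validation report
#' attached to the error condition (field `report`).
#'
#' @param model An `mdf_model`.
#' @param path Output path; when NULL the payload is returned (character
#'   for text encodings, raw for binary). When given, the encoding
#'   defaults to the file extension (.json/.yaml/.bin).
#' @param encoding One of `"json"`, `"yaml"`, `"binary"`.
#' @param validate Validate before writing (default TRUE).
#' @return The payload, or (with `path`) the path invisibly.
#' @export
write_model <- function(model, path = NULL,
                        encoding = c("json", "yaml", "binary"),
                        validate = TRUE) {
  if (!is.null(path) && missing(encoding)) encoding <- encoding_of_path(path)
  else encoding <- match.arg(encoding)
  if (validate) {
    rep <- validate_model(model)
    if (has_errors(rep))
      stop(structure(class = c("mdf_invalid_model", "error", "condition"),
                     list(message = paste0(
                       "refusing to write invalid model: ",
                       paste(rep$message[rep$severity == "error"],
                             collapse = "; ")),
                       call = NULL, report = rep)))
  }
  tree <- model_to_tree(model)
  payload <- switch(encoding,
                    json = tree_to_json(tree),
                    yaml = tree_to_yaml(tree),
                    binary = msgpack_pack(tree))
  if (is.null(path)) return(payload)
  if (encoding == "binary") writeBin(payload, path)
  else writeChar(payload, path, eos = NULL)
  invisible(path)
}

#' Read a model document
#'
#' Reads and validates a model from a file or an in-memory payload.
#' Unknown keys are preserved into the nearest `metadata` map with a
#' warning (forward compatibility); missing optional fields take their
#' schema defaults. A known key holding the wrong kind of value is a
#' schema violation (error), as is an unsupported format version.
#'
#' @param x File path, or a payload (character for text encodings, raw
#'   for binary).
#' @param encoding One of `"json"`, `"yaml"`, `"binary"`; inferred from
#'   the file extension when `x` is a path.
#' @param validate Run [validate_model()] and stop on errors (default
#'   TRUE).
#' @return An `mdf_model`.
#' @export
read_model <- function(x, encoding = NULL, validate = TRUE) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("[{}\n:]", x)) {
    if (is.null(encoding)) encoding <- encoding_of_path(x)
    payload <- if (encoding == "binary")
      readBin(x, raw(), n = file.info(x)$size)
    else readChar(x, file.info(x)$size, useBytes = TRUE)
  } else {
    payload <- x
    if (is.null(encoding))
      encoding <- if (is.raw(x)) "binary" else "json"
  }
  tree <- switch(encoding,
                 json = json_to_tree(payload),
                 yaml = yaml_to_tree(payload),
                 binary = msgpack_unpack(payload),
                 stop(sprintf("unknown encoding '%s'", encoding),
                      call. = FALSE))
  model <- tree_to_model(tree)
  if (validate) {
    rep <- validate_model(model)
    if (has_errors(rep))
      stop(structure(class = c("mdf_invalid_model", "error", "condition"),
                     list(message = paste0(
                       "document is not a valid model: ",
                       paste(rep$message[rep$severity == "error"],
                             collapse = "; ")),
                       call = NULL, report = rep)))
  }
  model
}

#' Convert a model document between encodings
#'
#' Reads a document and re-writes it in another encoding
#' (`read` then `write`); lossless across all encoding pairs. Converting
#' to the same encoding canonicalizes the document.
#'
#' @param path_in Input file.
#' @param encoding_out Target encoding (`"json"`, `"yaml"`, `"binary"`);
#'   inferred from `path_out` when omitted.
#' @param path_out Output file; defaults to `path_in` with the
#'   extension of the target encoding.
#' @return `path_out`, invisibly.
#' @export
convert_model <- function(path_in, encoding_out = NULL, path_out = NULL) {
  if (is.null(encoding_out)) {
    if (is.null(path_out)) stop("give encoding_out or path_out",
                                call. = FALSE)
    encoding_out <- encoding_of_path(path_out)
  }
  if (is.null(path_out)) {
    ext <- switch(encoding_out, json = ".json", yaml = ".yaml",
                  binary = ".bin")
    path_out <- paste0(sub("\\.(json|ya?ml|bin)$", "", path_in,
                           ignore.case = TRUE), ext)
  }
  model <- read_model(path_in)
  write_model(model, path_out, encoding_out)
  invisible(path_out)
}

#' Structural equality of two models
#'
#' Compares the canonical serialized trees of two models, which is the
#' format's own notion of equality (metadata included, component order
#' significant).
#'
#' @param a,b `mdf_model` objects.
#' @return Logical.
#' @export
models_equal <- function(a, b) {
  identical(write_model(a, encoding = "json", validate = FALSE),
            write_model(b, encoding = "json", validate = FALSE))
}
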