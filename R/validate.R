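# Structural validation, cycle detection and hierarchy flattening.

report_entry <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a model
#'
#' Checks every structural invariant of the document object model:
#' identifier grammar, id uniqueness, edge endpoint resolution, port
#' fan-in declarations, expression well-formedness, function-ontology
#' resolution, statefulness rules and subgraph boundary conventions.
#' Violations are returned as report rows, never raised; cycles are
#' legal and reported at severity `"info"` (they require
#' `default_initial_value` on every on-cycle sender port, which *is*
#' checked at severity `"error"`). Validation is pure: calling it twice
#' yields identical reports.
#'
#' @param model An `mdf_model`.
#' @param registry Function registry used to resolve function names
#'   (default [core_operator_set()]).
#' @return A data frame with columns `severity` (`"error"`, `"warning"`,
#'   `"info"`), `location`, `message`; class `mdf_validation_report`.
#'   Zero rows of severity error means the model is well-formed.
#' @export
validate_model <- function(model, registry = core_operator_set()) {
  rep <- list()
  add <- function(severity, location, message) {
    rep[[length(rep) + 1L]] <<- report_entry(severity, location, message)
  }
  if (!inherits(model, "mdf_model")) {
    add("error", "model", "not an mdf_model object")
  } else {
    if (!is_id(model$id %||% ""))
      add("error", "model", sprintf("invalid model id '%s'",
                                    as.character(model$id %||% "")))
    if (is.null(model$format_version) ||
        !nzchar(as.character(model$format_version)[1]))
      add("error", "model", "format_version missing")
    gids <- component_ids(model$graphs)
    if (anyDuplicated(gids))
      add("error", "model",
          sprintf("duplicate graph id '%s'", gids[duplicated(gids)][1]))
    for (g in model$graphs) validate_graph(g, paste0("graph ", g$id),
                                           registry, add)
  }
  out <- if (length(rep)) do.call(rbind, rep) else
    report_entry(character(0), character(0), character(0))
  class(out) <- c("mdf_validation_report", "data.frame")
  out
}

#' @export
print.mdf_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation: no findings\n")
  } else {
    for (i in seq_len(nrow(x)))
      cat(sprintf("[%s] %s: %s\n", x$severity[i], x$location[i],
                  x$message[i]))
  }
  invisible(x)
}

#' Does a validation report contain errors?
#' @param report An `mdf_validation_report`.
#' @return Logical.
#' @export
has_errors <- function(report) any(report$severity == "error")

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_graph <- function(g, loc, registry, add) {
  if (!is_id(g$id %||% ""))
    add("error", loc, sprintf("invalid graph id '%s'",
                              as.character(g$id %||% "")))
  nids <- component_ids(g$nodes)
  if (anyDuplicated(nids))
    add("error", loc, sprintf("duplicate node id '%s'",
                              nids[duplicated(nids)][1]))
  for (nd in g$nodes) validate_node(nd, paste0(loc, " node ", nd$id),
                                    registry, add)

  # edge endpoints
  seen_pairs <- character(0)
  targets <- list()  # receiver|port -> reduce mode & count
  for (e in g$edges) {
    eloc <- paste0(loc, " edge ", e$id %||% "?")
    if (!is_node_id(e$id %||% "")) add("error", eloc, "invalid edge id")
    snd <- find_by_id(g$nodes, e$sender %||% "")
    rcv <- find_by_id(g$nodes, e$receiver %||% "")
    if (is.null(snd)) {
      add("error", eloc, sprintf("sender node '%s' does not exist",
                                 as.character(e$sender %||% "")))
    } else if (is.null(find_by_id(snd$output_ports, e$sender_port %||% ""))) {
      add("error", eloc,
          sprintf("sender port '%s.%s' does not exist",
                  e$sender, as.character(e$sender_port %||% "")))
    }
    if (is.null(rcv)) {
      add("error", eloc, sprintf("receiver node '%s' does not exist",
                                 as.character(e$receiver %||% "")))
    } else if (is.null(find_by_id(rcv$input_ports, e$receiver_port %||% ""))) {
      add("error", eloc,
          sprintf("receiver port '%s.%s' does not exist",
                  e$receiver, as.character(e$receiver_port %||% "")))
    }
    key <- paste(e$sender, e$sender_port, e$receiver, e$receiver_port,
                 sep = "\r")
    if (key %in% seen_pairs)
      add("error", eloc, "duplicate edge between the same port pair")
    seen_pairs <- c(seen_pairs, key)
    if (!is.null(e$weight) && !(is.numeric(e$weight) &&
                                length(e$weight) == 1L))
      add("error", eloc, "edge weight must be a scalar")
    if (!is.null(rcv)) {
      tk <- paste(e$receiver, e$receiver_port, sep = "\r")
      targets[[tk]] <- (targets[[tk]] %||% 0L) + 1L
    }
  }
  for (tk in names(targets)) {
    if (targets[[tk]] > 1L) {
      parts <- strsplit(tk, "\r", fixed = TRUE)[[1]]
      rcv <- find_by_id(g$nodes, parts[1])
      port <- find_by_id(rcv$input_ports, parts[2])
      if (!identical(port$reduce, "sum"))
        add("error", loc,
            sprintf("input port '%s.%s' has %d incoming edges but reduce='error'; declare reduce='sum' for fan-in",
                    parts[1], parts[2], targets[[tk]]))
    }
  }

  # cycles: legal, flagged as info; every on-cycle sender port needs an
  # initial value so execution can start from committed previous values
  cycles <- detect_cycles(g)
  for (cy in cycles) {
    add("info", loc, paste0("cycle detected: ",
                            paste(c(cy, cy[1]), collapse = " -> ")))
    for (i in seq_along(cy)) {
      from <- cy[i]
      to <- cy[if (i == length(cy)) 1L else i + 1L]
      for (e in g$edges) {
        if (identical(e$sender, from) && identical(e$receiver, to)) {
          snd <- find_by_id(g$nodes, from)
          port <- find_by_id(snd$output_ports, e$sender_port)
          if (!is.null(port) && is.null(port$default_initial_value))
            add("error", paste0(loc, " edge ", e$id),
                sprintf("output port '%s.%s' feeds a cycle but has no default_initial_value",
                        from, e$sender_port))
        }
      }
    }
  }

  # conditions
  if (!is.null(g$conditions))
    validate_condition_set(g$conditions, g, loc, add)
}

validate_node <- function(nd, loc, registry, add) {
  if (!is_node_id(nd$id %||% ""))
    add("error", loc, sprintf("invalid node id '%s'",
                              as.character(nd$id %||% "")))
  local_ids <- c(component_ids(nd$input_ports),
                 component_ids(nd$parameters),
                 component_ids(nd$functions),
                 component_ids(nd$output_ports))
  if (anyDuplicated(local_ids))
    add("error", loc, sprintf("duplicate component id '%s' within node",
                              local_ids[duplicated(local_ids)][1]))
  for (cid in local_ids) {
    if (!is_id(cid))
      add("error", loc, sprintf("invalid component id '%s'", cid))
  }
  has_body <- length(nd$parameters) > 0L || length(nd$functions) > 0L
  if (!is.null(nd$subgraph)) {
    if (has_body)
      add("error", loc,
          "node has both a subgraph and parameters/functions; these are mutually exclusive")
    validate_graph(nd$subgraph, paste0(loc, " subgraph ", nd$subgraph$id),
                   registry, add)
    # boundary convention: each wrapper port maps to exactly one
    # like-named port on an inner node
    for (p in nd$input_ports) {
      owners <- Filter(function(inn)
        !is.null(find_by_id(inn$input_ports, p$id)), nd$subgraph$nodes)
      if (length(owners) != 1L)
        add("error", loc,
            sprintf("subgraph boundary input port '%s' matches %d inner ports (need exactly 1)",
                    p$id, length(owners)))
    }
    for (p in nd$output_ports) {
      owners <- Filter(function(inn)
        !is.null(find_by_id(inn$output_ports, p$id)), nd$subgraph$nodes)
      if (length(owners) != 1L)
        add("error", loc,
            sprintf("subgraph boundary output port '%s' matches %d inner ports (need exactly 1)",
                    p$id, length(owners)))
    }
    return(invisible(NULL))
  }

  for (p in nd$input_ports) {
    if (!is.null(p$shape) && any(p$shape <= 0))
      add("error", loc, sprintf("input port '%s' has non-positive shape",
                                p$id))
  }

  check_expr <- function(src, what) {
    tryCatch({
      parse_expression(src)
      TRUE
    }, error = function(e) {
      add("error", loc, sprintf("%s does not parse: %s", what,
                                conditionMessage(e)))
      FALSE
    })
  }

  slot_ids <- node_slot_ids(nd)
  known <- c(component_ids(nd$input_ports), slot_ids, BUILTIN_IDS)

  check_refs <- function(src, what) {
    ids <- tryCatch(free_identifiers(src), error = function(e) character(0))
    for (idn in setdiff(ids, known))
      add("error", loc,
          sprintf("%s references '%s', which is not defined in this node",
                  what, idn))
  }

  # parameters
  dep_edges <- list()
  for (p in nd$parameters) {
    what <- sprintf("parameter '%s'", p$id)
    stateful <- param_is_stateful(p)
    if (is.character(p$value) && check_expr(p$value, what)) {
      check_refs(p$value, what)
      deps <- setdiff(free_identifiers(p$value), c(p$id, BUILTIN_IDS))
      dep_edges[[p$id]] <- intersect(deps, slot_ids)
    } else {
      dep_edges[[p$id]] <- character(0)
    }
    if (!is.null(p$time_derivative) &&
        check_expr(p$time_derivative, paste0(what, " time_derivative")))
      check_refs(p$time_derivative, paste0(what, " time_derivative"))
    if (stateful && is.null(p$default_initial_value))
      add("error", loc,
          sprintf("stateful parameter '%s' requires default_initial_value",
                  p$id))
  }
  # function calls
  for (f in nd$functions) {
    what <- sprintf("function call '%s'", f$id)
    def <- tryCatch(lookup_function(registry, f[["function"]] %||% ""),
                    error = function(e) NULL)
    if (is.null(def)) {
      add("error", loc,
          sprintf("%s names unregistered function '%s'", what,
                  as.character(f[["function"]] %||% "")))
    } else {
      spec_names <- vapply(def$args, `[[`, "", "name")
      required <- spec_names[vapply(def$args, function(a)
        isTRUE(a$required), logical(1))]
      missing <- setdiff(required, names(f$args))
      for (m in missing)
        add("error", loc, sprintf("%s misses required argument '%s'",
                                  what, m))
      unknown <- setdiff(names(f$args), spec_names)
      for (u in unknown)
        add("error", loc, sprintf("%s supplies unknown argument '%s'",
                                  what, u))
    }
    deps <- character(0)
    for (an in names(f$args)) {
      src <- f$args[[an]]
      if (is.character(src) &&
          check_expr(src, sprintf("%s argument '%s'", what, an))) {
        check_refs(src, sprintf("%s argument '%s'", what, an))
        deps <- c(deps, free_identifiers(src))
      }
    }
    dep_edges[[f$id]] <- intersect(setdiff(unique(deps), f$id), slot_ids)
  }
  # non-stateful intra-node dependency graph must be acyclic (stateful
  # slots break cycles by reading previous values)
  stateful_ids <- component_ids(Filter(param_is_stateful, nd$parameters))
  nonstate <- setdiff(slot_ids, stateful_ids)
  cyc <- intra_node_cycle(dep_edges, nonstate)
  if (!is.null(cyc))
    add("error", loc,
        sprintf("intra-node cycle among non-stateful slots: %s",
                paste(cyc, collapse = " -> ")))
  # output ports
  for (op in nd$output_ports) {
    what <- sprintf("output port '%s'", op$id)
    if (is.null(op$value)) {
      add("error", loc, paste0(what, " has no value"))
    } else if (is.character(op$value) && check_expr(op$value, what)) {
      check_refs(op$value, what)
    }
  }
  invisible(NULL)
}

# DFS cycle search restricted to `restrict` vertices; returns one cycle
# (character vector) or NULL
intra_node_cycle <- function(dep_edges, restrict) {
  color <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return(invisible(NULL))
    assign(v, 1L, envir = color)
    path <<- c(path, v)
    for (w in intersect(dep_edges[[v]] %||% character(0), restrict)) {
      st <- if (exists(w, envir = color, inherits = FALSE))
        get(w, envir = color) else 0L
      if (st == 1L) {
        i <- match(w, path)
        found <<- c(path[i:length(path)], w)
      } else if (st == 0L) visit(w)
    }
    assign(v, 2L, envir = color)
    path <<- path[-length(path)]
    invisible(NULL)
  }
  for (v in restrict) {
    st <- if (exists(v, envir = color, inherits = FALSE))
      get(v, envir = color) else 0L
    if (st == 0L) visit(v)
    if (!is.null(found)) break
  }
  found
}

#' Enumerate elementary circuits of a graph
#'
#' Returns every elementary circuit (simple cycle) of the node-level
#' digraph induced by the edges. Each circuit is rotated to start at its
#' lexicographically smallest node id, and the list is ordered
#' lexicographically, so the output is deterministic.
#'
#' @param graph An `mdf_graph` whose edge endpoints resolve.
#' @return List of character vectors of node ids; empty for a DAG.
#' @examples
#' g <- mdf_graph("g",
#'   nodes = list(
#'     mdf_node("A", output_ports = list(mdf_output_port("o", "1")),
#'              input_ports = list(mdf_input_port("i"))),
#'     mdf_node("B", output_ports = list(mdf_output_port("o", "1")),
#'              input_ports = list(mdf_input_port("i")))),
#'   edges = list(mdf_edge("e1", "A", "o", "B", "i"),
#'                mdf_edge("e2", "B", "o", "A", "i")))
#' detect_cycles(g)
#' @export
detect_cycles <- function(graph) {
  nodes <- sort(component_ids(graph$nodes), method = "radix")
  rank <- stats::setNames(seq_along(nodes), nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) character(0))
  for (e in graph$edges) {
    s <- e$sender
    r <- e$receiver
    if (s %in% nodes && r %in% nodes && !(r %in% adj[[s]]))
      adj[[s]] <- sort(c(adj[[s]], r), method = "radix")
  }
  cycles <- list()
  # enumerate circuits whose smallest vertex is `start`, visiting only
  # vertices >= start (Johnson-style restriction keeps each circuit
  # unique and already rotation-normalized)
  for (start in nodes) {
    path <- start
    dfs <- function() {
      v <- path[length(path)]
      for (w in adj[[v]]) {
        if (w == start) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (rank[[w]] > rank[[start]] && !(w %in% path)) {
          path <<- c(path, w)
          dfs()
          path <<- path[-length(path)]
        }
      }
    }
    dfs()
  }
  keys <- vapply(cycles, function(cy) paste(cy, collapse = "\r"), "")
  cycles[order(keys, method = "radix")]
}

#' Flatten hierarchical composition
#'
#' Replaces every subgraph node by its namespaced contents: child ids
#' are prefixed `"parentid."`, inner edges and conditions are renamed
#' accordingly, and boundary edges are rewired to the inner node owning
#' the like-named port. A condition attached to a subgraph node is
#' conjoined (`and`) onto each flattened child's own condition. Inner
#' termination conditions are discarded — only the top-level termination
#' governs a run. The operation is idempotent and execution semantics
#' are preserved.
#'
#' @param model A valid `mdf_model`.
#' @return An `mdf_model` without subgraph nodes.
#' @export
flatten_hierarchy <- function(model) {
  model$graphs <- lapply(model$graphs, flatten_graph)
  model
}

flatten_graph <- function(g) {
  repeat {
    idx <- which(vapply(g$nodes, function(n) !is.null(n$subgraph),
                        logical(1)))
    if (length(idx) == 0L) return(g)
    i <- idx[1]
    g <- splice_subgraph(g, i)
  }
}

splice_subgraph <- function(g, i) {
  wrap <- g$nodes[[i]]
  inner <- flatten_graph(wrap$subgraph)
  pre <- paste0(wrap$id, ".")

  owner_of <- function(ports_field, pid) {
    for (inn in inner$nodes) {
      if (!is.null(find_by_id(inn[[ports_field]], pid)))
        return(inn$id)
    }
    stop(sprintf("unresolvable boundary port '%s' on subgraph node '%s'",
                 pid, wrap$id), call. = FALSE)
  }

  new_nodes <- lapply(inner$nodes, function(n) {
    n$id <- paste0(pre, n$id)
    n
  })
  new_edges <- lapply(inner$edges, function(e) {
    e$id <- paste0(pre, e$id)
    e$sender <- paste0(pre, e$sender)
    e$receiver <- paste0(pre, e$receiver)
    e
  })

  # rewire boundary edges of the outer graph
  outer_edges <- lapply(g$edges, function(e) {
    if (identical(e$receiver, wrap$id))
      e$receiver <- paste0(pre, owner_of("input_ports", e$receiver_port))
    if (identical(e$sender, wrap$id))
      e$sender <- paste0(pre, owner_of("output_ports", e$sender_port))
    e
  })

  nodes <- append(g$nodes[-i], new_nodes, after = i - 1L)
  g$nodes <- nodes
  g$edges <- c(outer_edges, new_edges)

  # namespace inner conditions; conjoin the wrapper's condition (if any)
  # onto every flattened child
  wrap_cond <- NULL
  if (!is.null(g$conditions) && !is.null(g$conditions$node_specific[[wrap$id]])) {
    wrap_cond <- g$conditions$node_specific[[wrap$id]]
    g$conditions$node_specific[[wrap$id]] <- NULL
  }
  inner_spec <- list()
  if (!is.null(inner$conditions))
    inner_spec <- inner$conditions$node_specific %||% list()
  upd <- g$conditions %||% mdf_condition_set()
  for (n in new_nodes) {
    bare <- substring(n$id, nchar(pre) + 1L)
    cond <- inner_spec[[bare]]
    if (!is.null(cond)) cond <- namespace_condition(cond, pre)
    if (!is.null(wrap_cond)) {
      cond <- if (is.null(cond)) wrap_cond else cond_and(cond, wrap_cond)
    }
    if (!is.null(cond)) upd$node_specific[[n$id]] <- cond
  }
  if (length(upd$node_specific) > 0L || !is.null(g$conditions))
    g$conditions <- upd
  g
}

namespace_condition <- function(cond, pre) {
  if (cond$type %in% c("every_n_calls", "after_n_calls", "before_n_calls"))
    cond$dep_node <- paste0(pre, cond$dep_node)
  if (cond$type == "threshold")
    cond$node <- paste0(pre, cond$node)
  if (cond$type %in% c("and", "or"))
    cond$terms <- lapply(cond$terms, namespace_condition, pre = pre)
  if (cond$type == "not")
    cond$inner <- namespace_condition(cond$inner, pre)
  cond
}
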