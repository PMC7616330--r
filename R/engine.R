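# Reference execution engine: evaluates nodes, propagates values along
# edges, integrates stateful parameters through simulated time (forward
# Euler, one scheduler pass per time step).
#
# Value lifecycle: each node owns committed values for its input ports,
# parameters, functions and output ports. During a pass, nodes execute
# in schedule order; a node's outputs are committed as soon as it
# finishes, so downstream nodes in the same pass read fresh values while
# any value crossing a cycle reads the previously committed one (or the
# sender port's default_initial_value before its first execution).

engine_state <- function(graph, dt = NULL, nonfinite_limit = 1000) {
  st <- new.env(parent = emptyenv())
  st$values <- new.env(parent = emptyenv())   # node -> env(slot -> value)
  for (nd in graph$nodes)
    assign(nd$id, new.env(parent = emptyenv()), envir = st$values)
  st$clock <- 0
  st$dt <- dt
  st$warnings <- new.env(parent = emptyenv())
  st$nonfinite_limit <- nonfinite_limit
  class(st) <- "mdf_engine_state"
  st
}

count_warning <- function(state, kind) {
  n <- if (exists(kind, envir = state$warnings, inherits = FALSE))
    get(kind, envir = state$warnings) else 0L
  assign(kind, n + 1L, envir = state$warnings)
  n + 1L
}

get_value <- function(state, node, slot) {
  env <- get(node, envir = state$values)
  if (exists(slot, envir = env, inherits = FALSE))
    get(slot, envir = env) else NULL
}

set_value <- function(state, node, slot, value) {
  assign(slot, value, envir = get(node, envir = state$values))
  invisible(NULL)
}

init_engine_values <- function(graph, state) {
  for (nd in graph$nodes) {
    for (p in nd$parameters) {
      if (param_is_stateful(p) && !is.null(p$default_initial_value))
        set_value(state, nd$id, p$id, as_value(p$default_initial_value))
      else if (is.numeric(p$value))
        set_value(state, nd$id, p$id, as_value(p$value))
    }
    for (op in nd$output_ports) {
      if (!is.null(op$default_initial_value))
        set_value(state, nd$id, op$id, as_value(op$default_initial_value))
    }
  }
}

as_value <- function(v) {
  if (is.null(dim(v))) as.numeric(v) else v
}

builtin_bindings <- function(state) {
  b <- list(time = state$clock)
  if (!is.null(state$dt)) b$dt <- state$dt
  b
}

# topological order of a node's parameter/function slots over their
# free-identifier dependencies; stateful slots and slots on a cycle made
# entirely of stateful slots read previous values (cycle broken)
node_slot_plan <- function(node) {
  slots <- c(node$parameters, node$functions)
  ids <- vapply(slots, `[[`, "", "id")
  stateful <- vapply(slots, function(s)
    inherits(s, "mdf_parameter") && param_is_stateful(s), logical(1))
  deps <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    d <- character(0)
    if (inherits(s, "mdf_function_call")) {
      for (a in s$args)
        if (is.character(a)) d <- c(d, free_identifiers(a))
    } else if (is.character(s$value)) {
      d <- free_identifiers(s$value)
    }
    # a dependency on a stateful slot is satisfied by its previous value
    d <- setdiff(unique(d), c(s$id, BUILTIN_IDS))
    d <- intersect(d, ids[!stateful])
    deps[[ids[i]]] <- d
  }
  order <- character(0)
  remaining <- ids
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(v)
      all(!(deps[[v]] %in% remaining)), logical(1))]
    if (length(ready) == 0L)
      stop(sprintf("intra-node cycle among non-stateful slots in node '%s'",
                   node$id), call. = FALSE)
    order <- c(order, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  list(order = order,
       slots = stats::setNames(slots, ids),
       stateful_ids = ids[stateful])
}

#' Evaluate a single node
#'
#' Evaluation order inside a node: input ports, then parameters and
#' function calls in intra-node dependency order (stateful slots read
#' their previously committed values, breaking cycles), then output
#' ports. Stateful updates are committed atomically at node completion.
#'
#' @param node An `mdf_node` (without subgraph).
#' @param incoming Named list mapping input-port ids to values.
#'   Unconnected/unsupplied ports read 0 with a warning counted on the
#'   state.
#' @param state Optional engine state (as created inside [run_model()]);
#'   when NULL a throwaway state is used, making the call pure.
#' @param registry Function registry.
#' @param plan Precomputed slot plan (internal; computed when NULL).
#' @return Named list mapping output-port ids to values.
#' @examples
#' nd <- mdf_node("n",
#'   input_ports = list(mdf_input_port("in1")),
#'   parameters = list(mdf_parameter("p", "2*in1")),
#'   output_ports = list(mdf_output_port("out", "p + 1")))
#' evaluate_node(nd, list(in1 = 3))
#' @export
evaluate_node <- function(node, incoming = list(), state = NULL,
                          registry = core_operator_set(), plan = NULL) {
  standalone <- is.null(state)
  if (standalone) {
    g <- mdf_graph("tmp", nodes = list(node))
    state <- engine_state(g)
    init_engine_values(g, state)
  }
  if (is.null(plan)) plan <- node_slot_plan(node)
  bindings <- builtin_bindings(state)
  for (p in node$input_ports) {
    v <- incoming[[p$id]]
    if (is.null(v)) {
      count_warning(state, paste0("unconnected_input:", node$id, ".", p$id))
      v <- 0
    }
    bindings[[p$id]] <- as_value(v)
    set_value(state, node$id, p$id, as_value(v))
  }
  # previous values of stateful slots are readable before recomputation
  for (sid in plan$stateful_ids) {
    prev <- get_value(state, node$id, sid)
    if (!is.null(prev)) bindings[[sid]] <- prev
  }
  new_state_values <- list()
  for (sid in plan$order) {
    s <- plan$slots[[sid]]
    v <- tryCatch({
      if (inherits(s, "mdf_function_call")) {
        args <- lapply(s$args, function(a) {
          if (is.character(a)) evaluate_expression(a, bindings, registry)
          else as_value(a)
        })
        apply_function(registry, s[["function"]], args)
      } else if (is.character(s$value)) {
        evaluate_expression(s$value, bindings, registry)
      } else if (!is.null(s$value)) {
        as_value(s$value)
      } else {
        # pure ODE state: value is carried, not recomputed
        bindings[[sid]] %||% 0
      }
    }, error = function(e) {
      stop(sprintf("node '%s', slot '%s': %s", node$id, sid,
                   conditionMessage(e)), call. = FALSE)
    })
    check_finite(state, v)
    if (sid %in% plan$stateful_ids) {
      # visible to later slots this pass, committed at completion
      new_state_values[[sid]] <- v
      bindings[[sid]] <- v
    } else {
      bindings[[sid]] <- v
      set_value(state, node$id, sid, v)
    }
  }
  outputs <- list()
  for (op in node$output_ports) {
    v <- tryCatch(
      evaluate_expression(op$value, bindings, registry),
      error = function(e)
        stop(sprintf("node '%s', output port '%s': %s", node$id, op$id,
                     conditionMessage(e)), call. = FALSE))
    check_finite(state, v)
    outputs[[op$id]] <- v
  }
  # atomic commit of stateful slots and outputs
  for (sid in names(new_state_values))
    set_value(state, node$id, sid, new_state_values[[sid]])
  for (oid in names(outputs))
    set_value(state, node$id, oid, outputs[[oid]])
  outputs
}

check_finite <- function(state, v) {
  if (is.numeric(v) && any(!is.finite(v))) {
    n <- count_warning(state, "nonfinite")
    if (n > state$nonfinite_limit)
      stop(sprintf("non-finite values exceeded limit (%d occurrences)", n),
           call. = FALSE)
  }
  invisible(NULL)
}

#' Advance simulated time by one Euler step
#'
#' Every parameter carrying a `time_derivative` advances by forward
#' Euler, `v <- v + dt * eval(time_derivative)`; all derivative
#' evaluations read pre-step values (simultaneous update), then the
#' clock advances by `dt`.
#'
#' @param graph An `mdf_graph`.
#' @param state Engine state with `dt` set.
#' @param registry Function registry.
#' @return The state, invisibly (mutated in place).
#' @export
step_time <- function(graph, state, registry = core_operator_set()) {
  if (is.null(state$dt)) stop("step_time requires dt", call. = FALSE)
  updates <- list()
  for (nd in graph$nodes) {
    for (p in nd$parameters) {
      if (is.null(p$time_derivative)) next
      bindings <- builtin_bindings(state)
      env <- get(nd$id, envir = state$values)
      for (slot in ls(env)) bindings[[slot]] <- get(slot, envir = env)
      d <- tryCatch(
        evaluate_expression(p$time_derivative, bindings, registry),
        error = function(e)
          stop(sprintf("node '%s', d(%s)/dt: %s", nd$id, p$id,
                       conditionMessage(e)), call. = FALSE))
      v <- get_value(state, nd$id, p$id) %||% 0
      updates[[length(updates) + 1L]] <- list(node = nd$id, slot = p$id,
                                              value = v + state$dt * d)
    }
  }
  for (u in updates) {
    check_finite(state, u$value)
    set_value(state, u$node, u$slot, u$value)
  }
  state$clock <- state$clock + state$dt
  invisible(state)
}

#' Execute a model
#'
#' Couples the condition-based scheduler with the numerical engine: each
#' pass executes the scheduled node set in dependency order, then (for
#' timed runs) advances every ODE state by one forward-Euler step and
#' increments the clock. The model is validated and flattened first.
#' With `seed` set, all stochastic functions draw from the run-level
#' seeded generator, making runs bit-reproducible.
#'
#' @param model An `mdf_model`.
#' @param dt Time step (> 0) in model time units; required with
#'   `duration`.
#' @param duration Simulated time to run for (exclusive with
#'   `max_passes`); the number of passes is `round(duration/dt)`.
#' @param max_passes Pass budget (exclusive with `duration`).
#' @param seed Optional integer seed.
#' @param record Character vector of `"node/slot"` names whose value is
#'   captured after each execution of the owning node (ODE states are
#'   additionally captured after each time step).
#' @param graph_id Graph to run (default: the model's first graph).
#' @param registry Function registry.
#' @param nonfinite_limit Number of non-finite values tolerated (counted
#'   as warnings) before the run errors.
#' @return An `mdf_run_result`: list with `trace` (pass, node, clock),
#'   `recorded` (per recorded slot, a list with `clock`, `pass` and
#'   `values`),
#'   `outcome` (`"terminated"` or `"budget_exhausted"`), `final_values`
#'   (committed slot values per node) and `warnings` (named counts).
#' @examples
#' m <- make_fixture("ffn_abc")
#' res <- run_model(m, max_passes = 1)
#' res$final_values$C$out  # 7
#' @export
run_model <- function(model, dt = NULL, duration = NULL, max_passes = NULL,
                      seed = NULL, record = character(0), graph_id = NULL,
                      registry = core_operator_set(),
                      nonfinite_limit = 1000) {
  rep <- validate_model(model, registry)
  if (has_errors(rep)) {
    msg <- paste(rep$message[rep$severity == "error"], collapse = "; ")
    stop(structure(class = c("mdf_invalid_model", "error", "condition"),
                   list(message = paste0("invalid model: ", msg),
                        call = NULL, report = rep)))
  }
  model <- flatten_hierarchy(model)
  if (is.null(graph_id)) {
    graph <- model$graphs[[1]]
  } else {
    graph <- find_by_id(model$graphs, graph_id)
    if (is.null(graph)) stop(sprintf("no graph '%s'", graph_id),
                             call. = FALSE)
  }
  if (is.null(duration) == is.null(max_passes))
    stop("exactly one of duration/max_passes must be given", call. = FALSE)
  if (!is.null(duration)) {
    if (is.null(dt) || dt <= 0) stop("duration requires dt > 0",
                                     call. = FALSE)
    n_passes <- max(1L, as.integer(round(duration / dt)))
  } else {
    n_passes <- as.integer(max_passes)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  est <- engine_state(graph, dt = dt, nonfinite_limit = nonfinite_limit)
  init_engine_values(graph, est)
  sst <- scheduler_state(graph, value_getter = function(node, parameter)
    get_value(est, node, parameter))

  rec <- parse_record_spec(record, graph)
  rec_data <- lapply(rec, function(r) {
    env <- new.env(parent = emptyenv())
    env$clock <- numeric(256L)
    env$pass <- integer(256L)
    env$values <- vector("list", 256L)
    env$n <- 0L
    env
  })
  record_slot <- function(i, pass) {
    r <- rec[[i]]
    v <- get_value(est, r$node, r$slot)
    d <- rec_data[[i]]
    d$n <- d$n + 1L
    if (d$n > length(d$clock)) {
      length(d$clock) <- 2L * length(d$clock)
      length(d$pass) <- 2L * length(d$pass)
      length(d$values) <- 2L * length(d$values)
    }
    d$clock[d$n] <- est$clock
    d$pass[d$n] <- pass
    d$values[[d$n]] <- v %||% NA_real_
  }

  nodes_by_id <- stats::setNames(graph$nodes, component_ids(graph$nodes))
  plans <- lapply(nodes_by_id, node_slot_plan)
  # termination condition defaults to all nodes having run; timed runs
  # are governed by the duration budget unless an explicit condition set
  # is declared
  cs <- graph$conditions %||%
    mdf_condition_set(termination = if (is.null(duration))
      cond_all_have_run() else cond_never())

  executor <- function(nid, sst) {
    nd <- nodes_by_id[[nid]]
    incoming <- gather_incoming(graph, nd, est)
    evaluate_node(nd, incoming, est, registry, plan = plans[[nid]])
    for (i in seq_along(rec))
      if (identical(rec[[i]]$node, nid) && !rec[[i]]$ode_only)
        record_slot(i, sst$pass_index)
  }
  on_pass_end <- function(sst) {
    if (!is.null(est$dt)) {
      step_time(graph, est, registry)
      sst$clock <- est$clock
      for (i in seq_along(rec))
        if (rec[[i]]$ode_only) record_slot(i, sst$pass_index)
    }
  }

  sched <- run_schedule(graph, cs, executor, max_passes = n_passes,
                        state = sst, on_pass_end = on_pass_end)
  # completing the requested duration is normal termination, not an
  # exhausted budget
  if (!is.null(duration) && sched$outcome == "budget_exhausted")
    sched$outcome <- "terminated"

  finals <- lapply(nodes_by_id, function(nd) {
    env <- get(nd$id, envir = est$values)
    vals <- lapply(stats::setNames(ls(env), ls(env)), get, envir = env)
    vals
  })
  warn <- lapply(stats::setNames(ls(est$warnings), ls(est$warnings)),
                 get, envir = est$warnings)
  rec_out <- lapply(rec_data, function(d)
    list(clock = d$clock[seq_len(d$n)], pass = d$pass[seq_len(d$n)],
         values = d$values[seq_len(d$n)]))
  structure(list(trace = sched$trace,
                 recorded = stats::setNames(rec_out, names(rec)),
                 outcome = sched$outcome,
                 final_values = finals,
                 warnings = warn,
                 clock = est$clock),
            class = "mdf_run_result")
}

#' @export
print.mdf_run_result <- function(x, ...) {
  cat(sprintf("<run result> outcome: %s; %d executions; clock: %g\n",
              x$outcome, nrow(x$trace), x$clock))
  if (length(x$recorded))
    cat("recorded:", paste(names(x$recorded), collapse = ", "), "\n")
  invisible(x)
}

parse_record_spec <- function(record, graph) {
  out <- list()
  for (r in record) {
    parts <- strsplit(r, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("record spec '%s' must be 'node/slot'", r),
           call. = FALSE)
    nd <- find_by_id(graph$nodes, parts[1])
    if (is.null(nd))
      stop(sprintf("record spec '%s': no node '%s'", r, parts[1]),
           call. = FALSE)
    p <- find_by_id(nd$parameters, parts[2])
    ode_only <- !is.null(p) && !is.null(p$time_derivative)
    out[[r]] <- list(node = parts[1], slot = parts[2], ode_only = ode_only)
  }
  out
}

gather_incoming <- function(graph, node, est) {
  incoming <- list()
  for (p in node$input_ports) {
    vals <- list()
    for (e in graph$edges) {
      if (identical(e$receiver, node$id) &&
          identical(e$receiver_port, p$id)) {
        v <- get_value(est, e$sender, e$sender_port)
        if (is.null(v)) {
          count_warning(est, paste0("unvalued_edge:", e$id))
          v <- 0
        }
        w <- e$weight %||% 1
        vals[[length(vals) + 1L]] <- v * w
      }
    }
    if (length(vals) == 1L) {
      incoming[[p$id]] <- vals[[1]]
    } else if (length(vals) > 1L) {
      incoming[[p$id]] <- Reduce(`+`, vals)
    }
  }
  incoming
}

#' Export recorded time series as CSV
#'
#' One column per recorded slot plus a leading `clock` column; one row
#' per recording event (a slot not recorded at a given clock value holds
#' NA). Array-valued slots are expanded to one column per element.
#'
#' @param result An `mdf_run_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_recorded_csv <- function(result, path) {
  rec <- result$recorded
  if (length(rec) == 0L) {
    utils::write.csv(data.frame(clock = numeric(0)), path,
                     row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  # rows are recording events keyed by (pass, clock); a slot without an
  # event on a row holds NA
  all_keys <- unique(do.call(rbind, lapply(rec, function(r)
    data.frame(pass = r$pass, clock = r$clock))))
  all_keys <- all_keys[order(all_keys$pass, all_keys$clock), , drop = FALSE]
  keyid <- paste(all_keys$pass, all_keys$clock, sep = "\r")
  cols <- list(clock = all_keys$clock)
  for (nm in names(rec)) {
    r <- rec[[nm]]
    width <- max(vapply(r$values, length, 1L))
    rkey <- paste(r$pass, r$clock, sep = "\r")
    for (k in seq_len(width)) {
      col <- rep(NA_real_, length(keyid))
      for (j in seq_along(r$clock)) {
        i <- match(rkey[j], keyid)
        v <- as.numeric(r$values[[j]])
        col[i] <- if (k <= length(v)) v[k] else NA_real_
      }
      cols[[if (width == 1L) nm else sprintf("%s[%d]", nm, k)]] <- col
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
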