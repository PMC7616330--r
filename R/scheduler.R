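# Condition-based scheduler: decides, pass by pass, which nodes execute.
#
# A *pass* is one scheduler iteration in which every node whose condition
# is satisfied executes once. Conditions are evaluated once per node per
# pass (no intra-pass re-evaluation). every_n_calls uses per-dependent
# consumption bookkeeping rather than a raw modulus, so a dependent that
# is itself gated never misses a firing of its dependency.

#' Condition constructors
#'
#' Declarative predicates governing when a node executes within a pass.
#' The vocabulary spans arbitrary execution order, multiple timescales
#' and cyclic graphs with a minimal orthogonal set:
#'
#' * `cond_always()`, `cond_never()` — constant predicates.
#' * `cond_every_n_calls(dep_node, n)` — fires once for each n-th call of
#'   `dep_node`, with per-dependent consumption bookkeeping: the
#'   predicate is true while unconsumed firings remain, so a node gated
#'   this way executes exactly `floor(calls(dep)/n)` times over a run. A
#'   slow node given `cond_every_n_calls(fast, k)` runs k-fold slower
#'   than `fast`.
#' * `cond_after_n_calls(dep_node, n)` — true once `dep_node` has run at
#'   least n times.
#' * `cond_before_n_calls(dep_node, n)` — true while `dep_node` has run
#'   fewer than n times.
#' * `cond_threshold(node, parameter, comparator, value)` — compares the
#'   last committed value of a (scalar) parameter; comparator one of
#'   `<, <=, >, >=, ==, !=`. Values are committed at the end of a node
#'   execution, never read mid-update.
#' * `cond_time_interval(start, end)` — true while the simulation clock
#'   is in `[start, end]`.
#' * `cond_and(...)`, `cond_or(...)`, `cond_not(x)` — composites.
#' * `cond_all_have_run()` — true once every node in the graph has
#'   executed at least once (the default termination condition).
#'
#' @param dep_node,node Node id referenced by the condition.
#' @param n Positive integer call count.
#' @param parameter Parameter id on `node`.
#' @param comparator One of `"<", "<=", ">", ">=", "==", "!="`.
#' @param value Numeric threshold.
#' @param start,end Clock bounds (either may be infinite).
#' @param ... Component conditions (at least one).
#' @param x Condition to negate.
#' @return An object of class `mdf_condition`.
#' @name conditions
NULL

new_cond <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "mdf_condition")
}

#' @rdname conditions
#' @export
cond_always <- function() new_cond("always")

#' @rdname conditions
#' @export
cond_never <- function() new_cond("never")

#' @rdname conditions
#' @export
cond_every_n_calls <- function(dep_node, n) {
  stopifnot(n >= 1)
  new_cond("every_n_calls", dep_node = dep_node, n = as.integer(n))
}

#' @rdname conditions
#' @export
cond_after_n_calls <- function(dep_node, n) {
  stopifnot(n >= 1)
  new_cond("after_n_calls", dep_node = dep_node, n = as.integer(n))
}

#' @rdname conditions
#' @export
cond_before_n_calls <- function(dep_node, n) {
  stopifnot(n >= 1)
  new_cond("before_n_calls", dep_node = dep_node, n = as.integer(n))
}

#' @rdname conditions
#' @export
cond_threshold <- function(node, parameter, comparator, value) {
  stopifnot(comparator %in% c("<", "<=", ">", ">=", "==", "!="))
  new_cond("threshold", node = node, parameter = parameter,
           comparator = comparator, value = as.numeric(value))
}

#' @rdname conditions
#' @export
cond_time_interval <- function(start = -Inf, end = Inf) {
  new_cond("time_interval", start = as.numeric(start), end = as.numeric(end))
}

#' @rdname conditions
#' @export
cond_and <- function(...) {
  terms <- list(...)
  stopifnot(length(terms) >= 1L)
  new_cond("and", terms = terms)
}

#' @rdname conditions
#' @export
cond_or <- function(...) {
  terms <- list(...)
  stopifnot(length(terms) >= 1L)
  new_cond("or", terms = terms)
}

#' @rdname conditions
#' @export
cond_not <- function(x) new_cond("not", inner = x)

#' @rdname conditions
#' @export
cond_all_have_run <- function() new_cond("all_have_run")

#' @export
print.mdf_condition <- function(x, ...) {
  cat("<condition>", condition_describe(x), "\n")
  invisible(x)
}

condition_describe <- function(c) {
  switch(c$type,
    always = "always",
    never = "never",
    every_n_calls = sprintf("every_n_calls(%s, %d)", c$dep_node, c$n),
    after_n_calls = sprintf("after_n_calls(%s, %d)", c$dep_node, c$n),
    before_n_calls = sprintf("before_n_calls(%s, %d)", c$dep_node, c$n),
    threshold = sprintf("threshold(%s.%s %s %g)", c$node, c$parameter,
                        c$comparator, c$value),
    time_interval = sprintf("time_interval(%g, %g)", c$start, c$end),
    and = paste0("and(", paste(vapply(c$terms, condition_describe, ""),
                               collapse = ", "), ")"),
    or = paste0("or(", paste(vapply(c$terms, condition_describe, ""),
                             collapse = ", "), ")"),
    not = paste0("not(", condition_describe(c$inner), ")"),
    all_have_run = "all_have_run",
    c$type)
}

#' Condition set for a graph
#'
#' @param node_specific Named list mapping node ids to conditions; nodes
#'   without an entry default to [cond_always()].
#' @param termination Termination condition, checked at the end of every
#'   pass (default [cond_all_have_run()]).
#' @return An object of class `mdf_condition_set`.
#' @export
mdf_condition_set <- function(node_specific = list(),
                              termination = cond_all_have_run()) {
  structure(list(node_specific = node_specific, termination = termination),
            class = "mdf_condition_set")
}

validate_condition_set <- function(cs, g, loc, add) {
  nids <- component_ids(g$nodes)
  for (nm in names(cs$node_specific)) {
    if (!(nm %in% nids))
      add("error", loc,
          sprintf("condition attached to nonexistent node '%s'", nm))
    validate_condition(cs$node_specific[[nm]], g, nids,
                       paste0(loc, " condition[", nm, "]"), add)
  }
  if (!is.null(cs$termination))
    validate_condition(cs$termination, g, nids,
                       paste0(loc, " termination"), add)
}

validate_condition <- function(c, g, nids, loc, add) {
  switch(c$type,
    every_n_calls = ,
    after_n_calls = ,
    before_n_calls = {
      if (!(c$dep_node %in% nids))
        add("error", loc, sprintf("references nonexistent node '%s'",
                                  c$dep_node))
      if (is.null(c$n) || c$n < 1L)
        add("error", loc, "n must be >= 1")
    },
    threshold = {
      nd <- find_by_id(g$nodes, c$node)
      if (is.null(nd)) {
        add("error", loc, sprintf("references nonexistent node '%s'",
                                  c$node))
      } else if (is.null(find_by_id(nd$parameters, c$parameter))) {
        add("error", loc,
            sprintf("references nonexistent parameter '%s.%s'", c$node,
                    c$parameter))
      }
      if (!(c$comparator %in% c("<", "<=", ">", ">=", "==", "!=")))
        add("error", loc, sprintf("invalid comparator '%s'",
                                  as.character(c$comparator)))
    },
    and = ,
    or = {
      if (length(c$terms) == 0L)
        add("error", loc, "composite condition with empty term list")
      for (t in c$terms) validate_condition(t, g, nids, loc, add)
    },
    not = validate_condition(c$inner, g, nids, loc, add),
    always = , never = , time_interval = , all_have_run = NULL,
    add("error", loc, sprintf("unknown condition type '%s'",
                              as.character(c$type)))
  )
}

#' Create a scheduler state
#'
#' Mutable record consulted by condition evaluation: pass index, per-node
#' call counts, the simulation clock (engine-owned) and a read-only view
#' of committed parameter values.
#'
#' @param graph The `mdf_graph` being scheduled.
#' @param value_getter Function `(node_id, parameter_id) -> value` giving
#'   the last committed parameter value (used by threshold conditions).
#' @return An environment of class `mdf_scheduler_state`.
#' @export
scheduler_state <- function(graph, value_getter = function(node, parameter) NULL) {
  st <- new.env(parent = emptyenv())
  st$pass_index <- 0L
  st$call_counts <- stats::setNames(integer(length(graph$nodes)),
                                    component_ids(graph$nodes))
  st$clock <- 0
  st$value_getter <- value_getter
  st$consumed <- new.env(parent = emptyenv())
  class(st) <- "mdf_scheduler_state"
  st
}

#' Evaluate a condition
#'
#' Pure predicate over the scheduler state (0/1). The scheduler itself
#' evaluates with consumption committing enabled, which is what makes
#' `every_n_calls` fire exactly once per n calls of its dependency; the
#' default here is a side-effect-free read.
#'
#' @param cond An `mdf_condition`.
#' @param state An `mdf_scheduler_state`.
#' @param dependent Id of the node whose schedule is being decided (keys
#'   the consumption bookkeeping).
#' @param commit Whether a true `every_n_calls` consumes its firing.
#' @return 0 or 1.
#' @export
is_satisfied <- function(cond, state, dependent = NULL, commit = FALSE) {
  cond_eval(cond, state, dependent %||% "", commit, "c")
}

cond_eval <- function(c, state, dependent, commit, path) {
  switch(c$type,
    always = 1,
    never = 0,
    every_n_calls = {
      calls <- state$call_counts[[c$dep_node]]
      if (is.null(calls))
        stop(sprintf("condition references unknown node '%s'", c$dep_node),
             call. = FALSE)
      key <- paste(dependent, path, sep = "\r")
      m <- if (exists(key, envir = state$consumed, inherits = FALSE))
        get(key, envir = state$consumed) else 0L
      avail <- calls %/% c$n
      sat <- avail > m
      if (sat && commit) assign(key, m + 1L, envir = state$consumed)
      as.numeric(sat)
    },
    after_n_calls = {
      calls <- state$call_counts[[c$dep_node]]
      if (is.null(calls))
        stop(sprintf("condition references unknown node '%s'", c$dep_node),
             call. = FALSE)
      as.numeric(calls >= c$n)
    },
    before_n_calls = {
      calls <- state$call_counts[[c$dep_node]]
      if (is.null(calls))
        stop(sprintf("condition references unknown node '%s'", c$dep_node),
             call. = FALSE)
      as.numeric(calls < c$n)
    },
    threshold = {
      v <- state$value_getter(c$node, c$parameter)
      if (is.null(v))
        stop(sprintf("threshold condition references unresolved '%s.%s'",
                     c$node, c$parameter), call. = FALSE)
      v <- as.numeric(v)[1]
      as.numeric(switch(c$comparator,
        "<" = v < c$value, "<=" = v <= c$value,
        ">" = v > c$value, ">=" = v >= c$value,
        "==" = v == c$value, "!=" = v != c$value))
    },
    time_interval = as.numeric(state$clock >= c$start &&
                                 state$clock <= c$end),
    and = {
      r <- 1
      for (i in seq_along(c$terms)) {
        r <- r * cond_eval(c$terms[[i]], state, dependent, commit,
                           paste0(path, "/", i))
      }
      as.numeric(r > 0)
    },
    or = {
      r <- 0
      for (i in seq_along(c$terms)) {
        r <- max(r, cond_eval(c$terms[[i]], state, dependent, commit,
                              paste0(path, "/", i)))
      }
      as.numeric(r > 0)
    },
    not = as.numeric(cond_eval(c$inner, state, dependent, commit,
                               paste0(path, "/!")) == 0),
    all_have_run = as.numeric(all(state$call_counts >= 1L)),
    stop(sprintf("unknown condition type '%s'", as.character(c$type)),
         call. = FALSE)
  )
}

cond_for_node <- function(condition_set, node_id) {
  if (is.null(condition_set)) return(cond_always())
  condition_set$node_specific[[node_id]] %||% cond_always()
}

#' Next execution set for a pass
#'
#' Nodes are considered in the graph's static order — data-dependency
#' order for acyclic dependencies (sender before receiver), ties broken
#' by declaration order, dependency cycles in declaration order reading
#' previous-pass values — and each node's condition is evaluated exactly
#' once per pass, in that sequence, seeing the call counts of nodes
#' selected earlier in the same pass. A node gated by
#' `every_n_calls(dep, n)` therefore runs in the *same* pass as the
#' dependency call that completes a group of n.
#'
#' @param graph An `mdf_graph`.
#' @param condition_set An `mdf_condition_set` (or NULL for all-always).
#' @param state An `mdf_scheduler_state`; consumption bookkeeping is
#'   committed.
#' @param static_order Precomputed static order (internal; computed when
#'   NULL).
#' @return Character vector of node ids in execution order.
#' @export
next_execution_set <- function(graph, condition_set, state,
                               static_order = NULL) {
  order <- static_order %||% graph_static_order(graph)
  selected <- character(0)
  saved_counts <- state$call_counts
  for (nid in order) {
    if (is_satisfied(cond_for_node(condition_set, nid), state,
                     dependent = nid, commit = TRUE) > 0) {
      selected <- c(selected, nid)
      # later conditions this pass see this execution-to-be
      state$call_counts[[nid]] <- state$call_counts[[nid]] + 1L
    }
  }
  # the caller (run_schedule) performs the real executions and count
  # increments; restore the working copy
  state$call_counts <- saved_counts
  selected
}

# Kahn's algorithm over the whole graph with a declaration-order queue;
# when only cyclic nodes remain, the earliest-declared one is released
# (cycle members thus come out in declaration order, reading
# previous-pass values at execution time)
graph_static_order <- function(graph) {
  nids <- component_ids(graph$nodes)
  if (length(nids) <= 1L) return(nids)
  deps <- stats::setNames(vector("list", length(nids)), nids)
  for (e in graph$edges) {
    if (e$sender %in% nids && e$receiver %in% nids &&
        e$sender != e$receiver)
      deps[[e$receiver]] <- union(deps[[e$receiver]], e$sender)
  }
  remaining <- nids
  out <- character(0)
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(v)
      length(setdiff(deps[[v]], remaining)) == length(deps[[v]]),
      logical(1))]
    nxt <- if (length(ready) > 0L) ready[1] else remaining[1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

#' Run a schedule
#'
#' Repeatedly applies [next_execution_set()], invoking `executor` for
#' each scheduled node, until the termination condition is satisfied (at
#' end of pass) or `max_passes` is exhausted — reported as distinct
#' outcomes.
#'
#' @param graph An `mdf_graph`.
#' @param condition_set An `mdf_condition_set` (NULL for defaults).
#' @param executor Function `(node_id, state)` called per execution; an
#'   error aborts the run with the partial trace attached to the
#'   condition (field `trace`).
#' @param max_passes Pass budget (>= 1), guarding non-terminating
#'   schedules.
#' @param state Optional pre-built [scheduler_state()].
#' @param on_pass_end Optional callback `(state)` run after each pass
#'   (the engine advances simulated time here).
#' @return List with `trace` (data frame: pass, node, clock), `outcome`
#'   (`"terminated"` or `"budget_exhausted"`) and `state`.
#' @export
run_schedule <- function(graph, condition_set = NULL, executor,
                         max_passes, state = NULL, on_pass_end = NULL) {
  stopifnot(max_passes >= 1)
  if (is.null(state)) state <- scheduler_state(graph)
  cs <- condition_set %||% mdf_condition_set()
  cap <- 256L
  tr_pass <- integer(cap)
  tr_node <- character(cap)
  tr_clock <- numeric(cap)
  n_tr <- 0L
  static_order <- graph_static_order(graph)
  outcome <- "budget_exhausted"
  repeat {
    todo <- next_execution_set(graph, cs, state, static_order)
    for (nid in todo) {
      tryCatch(executor(nid, state), error = function(e) {
        idx <- seq_len(n_tr)
        stop(structure(class = c("mdf_execution_error", "error", "condition"),
                       list(message = sprintf("executor failed at node '%s': %s",
                                              nid, conditionMessage(e)),
                            call = NULL,
                            trace = data.frame(pass = tr_pass[idx],
                                               node = tr_node[idx],
                                               clock = tr_clock[idx],
                                               stringsAsFactors = FALSE))))
      })
      state$call_counts[[nid]] <- state$call_counts[[nid]] + 1L
      n_tr <- n_tr + 1L
      if (n_tr > cap) {
        cap <- cap * 2L
        length(tr_pass) <- cap
        length(tr_node) <- cap
        length(tr_clock) <- cap
      }
      tr_pass[n_tr] <- state$pass_index
      tr_node[n_tr] <- nid
      tr_clock[n_tr] <- state$clock
    }
    if (!is.null(on_pass_end)) on_pass_end(state)
    state$pass_index <- state$pass_index + 1L
    term <- !is.null(cs$termination) &&
      is_satisfied(cs$termination, state, dependent = ".termination",
                   commit = TRUE) > 0
    if (term) {
      outcome <- "terminated"
      break
    }
    if (state$pass_index >= max_passes) break
  }
  idx <- seq_len(n_tr)
  list(trace = data.frame(pass = tr_pass[idx], node = tr_node[idx],
                          clock = tr_clock[idx], stringsAsFactors = FALSE),
       outcome = outcome, state = state)
}

#' Write an execution trace as CSV
#'
#' @param trace Data frame with columns pass, node, clock (as returned in
#'   `run_schedule()$trace` or `run_model()$trace`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("pass", "node", "clock")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
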