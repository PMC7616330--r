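# Independent oracles used across the suite. Each reimplements the
# checked behaviour by the most direct route available (explicit loops,
# closed forms, brute-force replay), sharing no code with the package
# internals it checks.

# ---- naive array-operator oracles (explicit loops) ------------------------

oracle_matmul <- function(a, b) {
  A <- if (is.null(dim(a))) matrix(a, nrow = 1) else a
  B <- if (is.null(dim(b))) matrix(b, ncol = 1) else b
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  if (is.null(dim(a)) || is.null(dim(b))) as.numeric(out) else out
}

oracle_elementwise <- function(f) function(x) {
  out <- x
  for (i in seq_along(x)) out[i] <- f(x[i])
  storage.mode(out) <- "double"
  out
}

oracle_binary <- function(f) function(a, b) {
  if (length(a) == 1 && is.null(dim(a))) {
    out <- b
    for (i in seq_along(b)) out[i] <- f(a, b[i])
  } else if (length(b) == 1 && is.null(dim(b))) {
    out <- a
    for (i in seq_along(a)) out[i] <- f(a[i], b)
  } else {
    out <- a
    for (i in seq_along(a)) out[i] <- f(a[i], b[i])
  }
  storage.mode(out) <- "double"
  out
}

oracle_softmax_vec <- function(v) {
  e <- numeric(length(v))
  for (i in seq_along(v)) e[i] <- exp(v[i] - max(v))
  e / sum(e)
}

oracle_softmax <- function(x, axis = NULL) {
  if (is.null(dim(x))) return(oracle_softmax_vec(x))
  if (is.null(axis)) axis <- 2L
  out <- x
  if (axis == 2L) {
    for (i in seq_len(nrow(x))) out[i, ] <- oracle_softmax_vec(x[i, ])
  } else {
    for (j in seq_len(ncol(x))) out[, j] <- oracle_softmax_vec(x[, j])
  }
  out
}

oracle_reduce <- function(f) function(x, axes = NULL) {
  if (is.null(dim(x)) || is.null(axes)) return(f(as.numeric(x)))
  d <- dim(x)
  keep <- setdiff(seq_along(d), axes)
  if (length(keep) == 0L) return(f(as.numeric(x)))
  stopifnot(length(d) == 2L)  # matrix cases only in these tests
  if (identical(keep, 1L)) {
    out <- numeric(d[1])
    for (i in seq_len(d[1])) out[i] <- f(x[i, ])
  } else {
    out <- numeric(d[2])
    for (j in seq_len(d[2])) out[j] <- f(x[, j])
  }
  out
}

oracle_transpose <- function(x) {
  if (is.null(dim(x))) return(x)
  out <- matrix(0, ncol(x), nrow(x))
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      out[j, i] <- x[i, j]
  out
}

oracle_clip <- function(x, lo, hi) {
  out <- x
  for (i in seq_along(x))
    out[i] <- if (x[i] < lo) lo else if (x[i] > hi) hi else x[i]
  storage.mode(out) <- "double"
  out
}

oracle_reshape_rowmajor <- function(x, shape) {
  # flatten row-major with explicit index loops, then refill
  flat <- numeric(length(x))
  if (is.null(dim(x))) {
    flat <- as.numeric(x)
  } else {
    k <- 1L
    for (i in seq_len(nrow(x)))
      for (j in seq_len(ncol(x))) {
        flat[k] <- x[i, j]
        k <- k + 1L
      }
  }
  if (length(shape) == 1L) return(flat)
  out <- matrix(0, shape[1], shape[2])
  k <- 1L
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2])) {
      out[i, j] <- flat[k]
      k <- k + 1L
    }
  out
}

# ---- random expression ASTs (paired rendering) ----------------------------
# Builds a random expression tree and renders it twice: once in the
# package grammar, once as base-R source. Evaluating the R rendering with
# eval(parse(...)) is the recursive-descent oracle.

random_expr <- function(depth, vars) {
  if (depth <= 0 || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.5) {
      v <- sample(vars, 1)
      return(list(mdf = v, r = v))
    }
    k <- round(stats::runif(1, 0.1, 4), 3)
    return(list(mdf = format(k), r = format(k)))
  }
  pick <- sample(c("+", "-", "*", "/", "**", "neg", "cmp"), 1,
                 prob = c(4, 4, 4, 2, 1, 2, 1))
  if (pick == "neg") {
    a <- random_expr(depth - 1, vars)
    return(list(mdf = paste0("-(", a$mdf, ")"),
                r = paste0("-(", a$r, ")")))
  }
  a <- random_expr(depth - 1, vars)
  b <- random_expr(depth - 1, vars)
  if (pick == "cmp") {
    op <- sample(c("<", "<=", ">", ">=", "==", "!="), 1)
    return(list(mdf = paste0("(", a$mdf, ") ", op, " (", b$mdf, ")"),
                r = paste0("as.numeric((", a$r, ") ", op, " (", b$r, "))")))
  }
  rop <- if (pick == "**") "^" else pick
  list(mdf = paste0("(", a$mdf, ") ", pick, " (", b$mdf, ")"),
       r = paste0("(", a$r, ") ", rop, " (", b$r, ")"))
}

# ---- brute-force scheduler replay oracle ----------------------------------
# Naive reimplementation of the stated pass semantics: nodes considered
# in dependency-then-declaration order; each condition evaluated once per
# pass in sequence, seeing earlier-in-pass selections; every_n_calls
# consumes one firing per true evaluation; termination checked at end of
# pass.

replay_static_order <- function(node_ids, edge_list) {
  preds <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (e in edge_list)
    if (e$from != e$to)
      preds[[e$to]] <- unique(c(preds[[e$to]], e$from))
  remaining <- node_ids
  out <- character(0)
  while (length(remaining)) {
    placed <- FALSE
    for (v in remaining) {
      if (!any(preds[[v]] %in% remaining)) {
        out <- c(out, v)
        remaining <- setdiff(remaining, v)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      out <- c(out, remaining[1])
      remaining <- remaining[-1]
    }
  }
  out
}

replay_cond <- function(c, calls, consumed, key, clock) {
  # returns list(sat, consumed)
  r <- function(cc, k) replay_cond(cc, calls, consumed, k, clock)
  switch(c$type,
    always = list(sat = TRUE, consumed = consumed),
    never = list(sat = FALSE, consumed = consumed),
    after_n_calls = list(sat = calls[[c$dep_node]] >= c$n,
                         consumed = consumed),
    before_n_calls = list(sat = calls[[c$dep_node]] < c$n,
                          consumed = consumed),
    every_n_calls = {
      m <- consumed[[key]]
      if (is.null(m)) m <- 0L
      sat <- (calls[[c$dep_node]] %/% c$n) > m
      if (sat) consumed[[key]] <- m + 1L
      list(sat = sat, consumed = consumed)
    },
    time_interval = list(sat = clock >= c$start && clock <= c$end,
                         consumed = consumed),
    and = {
      sat <- TRUE
      for (i in seq_along(c$terms)) {
        res <- replay_cond(c$terms[[i]], calls, consumed,
                           paste0(key, "/", i), clock)
        consumed <- res$consumed
        sat <- sat && res$sat
      }
      list(sat = sat, consumed = consumed)
    },
    or = {
      sat <- FALSE
      for (i in seq_along(c$terms)) {
        res <- replay_cond(c$terms[[i]], calls, consumed,
                           paste0(key, "/", i), clock)
        consumed <- res$consumed
        sat <- sat || res$sat
      }
      list(sat = sat, consumed = consumed)
    },
    not = {
      res <- replay_cond(c$inner, calls, consumed, paste0(key, "/!"),
                         clock)
      list(sat = !res$sat, consumed = res$consumed)
    },
    all_have_run = list(sat = all(unlist(calls) >= 1L),
                        consumed = consumed),
    stop("replay oracle: unsupported condition type ", c$type)
  )
}

replay_schedule <- function(node_ids, edge_list, node_conds, termination,
                            max_passes) {
  order <- replay_static_order(node_ids, edge_list)
  calls <- as.list(stats::setNames(rep(0L, length(node_ids)), node_ids))
  consumed <- list()
  trace <- data.frame(pass = integer(0), node = character(0),
                      stringsAsFactors = FALSE)
  outcome <- "budget_exhausted"
  for (pass in seq_len(max_passes) - 1L) {
    for (nid in order) {
      cond <- node_conds[[nid]]
      if (is.null(cond)) cond <- list(type = "always")
      res <- replay_cond(cond, calls, consumed, paste0(nid, "#c"), 0)
      consumed <- res$consumed
      if (res$sat) {
        calls[[nid]] <- calls[[nid]] + 1L
        trace <- rbind(trace, data.frame(pass = pass, node = nid,
                                         stringsAsFactors = FALSE))
      }
    }
    res <- replay_cond(termination, calls, consumed, "#term", 0)
    consumed <- res$consumed
    if (res$sat) {
      outcome <- "terminated"
      break
    }
  }
  list(trace = trace, outcome = outcome)
}

# random condition over a node-id universe (call-count based only, so
# the replay oracle needs no engine values)
random_condition <- function(node_ids, depth = 2) {
  if (depth <= 0 || stats::runif(1) < 0.4) {
    t <- sample(c("always", "never", "every_n_calls", "after_n_calls",
                  "before_n_calls"), 1, prob = c(3, 1, 3, 2, 2))
    return(switch(t,
      always = cond_always(),
      never = cond_never(),
      every_n_calls = cond_every_n_calls(sample(node_ids, 1),
                                         sample(1:3, 1)),
      after_n_calls = cond_after_n_calls(sample(node_ids, 1),
                                         sample(1:4, 1)),
      before_n_calls = cond_before_n_calls(sample(node_ids, 1),
                                           sample(1:4, 1))))
  }
  t <- sample(c("and", "or", "not"), 1)
  switch(t,
    and = cond_and(random_condition(node_ids, depth - 1),
                   random_condition(node_ids, depth - 1)),
    or = cond_or(random_condition(node_ids, depth - 1),
                 random_condition(node_ids, depth - 1)),
    not = cond_not(random_condition(node_ids, depth - 1)))
}

# condition object -> the plain-list form the replay oracle consumes
cond_as_list <- function(c) {
  out <- unclass(c)
  if (!is.null(out$terms)) out$terms <- lapply(out$terms, cond_as_list)
  if (!is.null(out$inner)) out$inner <- cond_as_list(out$inner)
  out
}

# edge list (from/to) of a model's first graph
graph_edge_list <- function(model) {
  g <- flatten_hierarchy(model)$graphs[[1]]
  lapply(g$edges, function(e) list(from = e$sender, to = e$receiver))
}

graph_node_ids <- function(model) {
  g <- flatten_hierarchy(model)$graphs[[1]]
  vapply(g$nodes, function(n) n$id, "")
}

# ---- tiny JSON-Schema subset checker --------------------------------------
# Understands: type (string or vector), properties, required,
# patternProperties, enum, items, minProperties, maxProperties, $ref into
# #/definitions. Enough to exercise the shipped schemas against fixtures.

schema_check <- function(instance, schema, root = schema, path = "$") {
  fail <- function(msg) stop(sprintf("%s: %s", path, msg), call. = FALSE)
  if (!is.null(schema[["$ref"]])) {
    ref <- sub("^#/definitions/", "", schema[["$ref"]])
    return(schema_check(instance, root$definitions[[ref]], root, path))
  }
  types <- schema$type
  if (!is.null(types)) {
    t_of <- function(x) {
      if (is.list(x)) {
        if (!is.null(names(x)) || length(x) == 0L) "object" else "array"
      } else if (is.character(x)) "string"
      else if (is.numeric(x)) "number"
      else if (is.logical(x)) "boolean"
      else "null"
    }
    actual <- t_of(instance)
    # an unnamed empty list is ambiguous; accept either container kind
    ok <- actual %in% unlist(types) ||
      (is.list(instance) && length(instance) == 0L &&
         any(c("object", "array") %in% unlist(types)))
    if (!ok) fail(sprintf("expected type %s, got %s",
                          paste(unlist(types), collapse = "|"), actual))
  }
  if (!is.null(schema$enum)) {
    if (!any(vapply(schema$enum, identical, logical(1), y = instance)))
      fail("value not in enum")
  }
  if (is.list(instance) && !is.null(names(instance))) {
    for (req in unlist(schema$required))
      if (!(req %in% names(instance)))
        fail(sprintf("missing required key '%s'", req))
    if (!is.null(schema$minProperties) &&
        length(instance) < schema$minProperties)
      fail("too few properties")
    if (!is.null(schema$maxProperties) &&
        length(instance) > schema$maxProperties)
      fail("too many properties")
    for (k in names(instance)) {
      sub <- schema$properties[[k]]
      if (is.null(sub) && !is.null(schema$patternProperties)) {
        for (pat in names(schema$patternProperties)) {
          if (grepl(pat, k)) {
            sub <- schema$patternProperties[[pat]]
            break
          }
        }
      }
      if (!is.null(sub))
        schema_check(instance[[k]], sub, root, paste0(path, ".", k))
    }
  }
  if (is.list(instance) && is.null(names(instance)) &&
      !is.null(schema$items)) {
    for (i in seq_along(instance))
      schema_check(instance[[i]], schema$items, root,
                   sprintf("%s[%d]", path, i))
  }
  invisible(TRUE)
}

read_json_tree <- function(path_or_text) {
  jsonlite::parse_json(path_or_text)
}

# ---- misc -----------------------------------------------------------------

run_final <- function(model, ...) run_model(model, ...)$final_values

expect_close <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
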