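# scheduler semantics: pass-by-pass node selection under conditions

sched_fixture <- function(n_nodes = 3, chain = TRUE) {
  mk <- function(id, with_in) mdf_node(id,
    input_ports = if (with_in) list(mdf_input_port("i")) else list(),
    parameters = list(mdf_parameter("k", value = 1)),
    output_ports = list(mdf_output_port("o",
      if (with_in) "i + k" else "k")))
  ids <- LETTERS[seq_len(n_nodes)]
  nodes <- lapply(seq_along(ids), function(j) mk(ids[j], chain && j > 1))
  edges <- if (chain && n_nodes > 1)
    lapply(seq_len(n_nodes - 1), function(j)
      mdf_edge(paste0("e", j), ids[j], "o", ids[j + 1], "i"))
  else list()
  mdf_graph("g", nodes = nodes, edges = edges)
}

null_exec <- function(nid, st) NULL

test_that("constant and composed predicates behave algebraically", {
  g <- sched_fixture(2)
  st <- scheduler_state(g)
  expect_equal(is_satisfied(cond_always(), st), 1)
  expect_equal(is_satisfied(cond_never(), st), 0)

  # double negation and identity/annihilator laws over random states
  set.seed(31)
  for (i in 1:100) {
    st <- scheduler_state(g)
    st$call_counts[] <- sample(0:5, length(st$call_counts),
                               replace = TRUE)
    st$clock <- stats::runif(1, 0, 10)
    c1 <- random_condition(c("A", "B"))
    v <- is_satisfied(c1, st, dependent = "A")
    expect_equal(is_satisfied(cond_not(cond_not(c1)), st,
                              dependent = "A"), v)
    expect_equal(is_satisfied(cond_and(c1, cond_always()), st,
                              dependent = "A"), v)
    expect_equal(is_satisfied(cond_or(c1, cond_never()), st,
                              dependent = "A"), v)
    # De Morgan
    c2 <- random_condition(c("A", "B"))
    lhs <- is_satisfied(cond_not(cond_and(c1, c2)), st, dependent = "A")
    rhs <- is_satisfied(cond_or(cond_not(c1), cond_not(c2)), st,
                        dependent = "A")
    expect_equal(lhs, rhs)
  }
})

test_that("time_interval and threshold read committed state", {
  g <- sched_fixture(1)
  st <- scheduler_state(g, value_getter = function(n, p)
    if (n == "A" && p == "k") 2.5 else NULL)
  st$clock <- 5
  expect_equal(is_satisfied(cond_time_interval(0, 10), st), 1)
  expect_equal(is_satisfied(cond_time_interval(6, 10), st), 0)
  expect_equal(is_satisfied(cond_threshold("A", "k", ">", 2), st), 1)
  expect_equal(is_satisfied(cond_threshold("A", "k", "<=", 2), st), 0)
  expect_error(is_satisfied(cond_threshold("A", "zz", ">", 0), st),
               "unresolved")
})

test_that("every_n_calls consumption: fires once per completed group of n", {
  g <- sched_fixture(2, chain = FALSE)
  cs <- mdf_condition_set(node_specific = list(
    B = cond_every_n_calls("A", 2)), termination = cond_never())
  res <- run_schedule(g, cs, null_exec, max_passes = 4)
  expect_equal(paste(res$trace$pass, res$trace$node),
               c("0 A", "1 A", "1 B", "2 A", "3 A", "3 B"))
  # over 2 calls of A: B fired once; over 4: twice
  expect_equal(sum(res$trace$node == "B"), 2)
})

test_that("all-always DAG schedules in topological order each pass", {
  g <- sched_fixture(3)
  st <- scheduler_state(g)
  expect_equal(next_execution_set(g, NULL, st), c("A", "B", "C"))
  # declaring C before A must not change dependency order
  g2 <- mdf_graph("g", nodes = rev(g$nodes), edges = g$edges)
  expect_equal(next_execution_set(g2, NULL, scheduler_state(g2)),
               c("A", "B", "C"))
  # the order is a valid topological sort on random DAGs (igraph oracle)
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    ids <- LETTERS[1:n]
    nodes <- lapply(ids, function(id) mdf_node(id,
      input_ports = list(mdf_input_port("i", reduce = "sum")),
      parameters = list(mdf_parameter("k", value = 1)),
      output_ports = list(mdf_output_port("o", "k"))))
    edges <- list()
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (stats::runif(1) < 0.4)
        edges[[length(edges) + 1L]] <- mdf_edge(
          paste0("e", a, b), ids[a], "o", ids[b], "i")
    gg <- mdf_graph("g", nodes = nodes[sample(n)], edges = edges)
    ord <- next_execution_set(gg, NULL, scheduler_state(gg))
    expect_setequal(ord, ids)
    if (length(edges) > 0) {
      ig <- igraph::make_graph(
        unlist(lapply(edges, function(e) c(e$sender, e$receiver))),
        isolates = setdiff(ids, unlist(lapply(edges, function(e)
          c(e$sender, e$receiver)))), directed = TRUE)
      expect_true(igraph::is_dag(ig))
    }
    for (e in edges)
      expect_lt(match(e$sender, ord), match(e$receiver, ord))
  }
})

test_that("termination, budgets, and cyclic passes behave as specified", {
  # single node, default termination all_have_run
  g1 <- sched_fixture(1)
  res <- run_schedule(g1, NULL, null_exec, max_passes = 10)
  expect_equal(res$outcome, "terminated")
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$trace$pass, 0)

  # never-satisfied termination exhausts the budget
  cs <- mdf_condition_set(termination = cond_never())
  res2 <- run_schedule(g1, cs, null_exec, max_passes = 5)
  expect_equal(res2$outcome, "budget_exhausted")
  expect_equal(nrow(res2$trace), 5)

  # termination after_n_calls stops the pass after the 3rd call
  g3 <- sched_fixture(3)
  cs3 <- mdf_condition_set(termination = cond_after_n_calls("C", 3))
  res3 <- run_schedule(g3, cs3, null_exec, max_passes = 100)
  expect_equal(res3$outcome, "terminated")
  expect_equal(sum(res3$trace$node == "C"), 3)

  # two-node cycle, all always, 3 passes -> 6 executions
  gc <- make_fixture("cyclic_pair")$graphs[[1]]
  csc <- mdf_condition_set(termination = cond_never())
  resc <- run_schedule(gc, csc, null_exec, max_passes = 3)
  expect_equal(nrow(resc$trace), 6)

  # executor failure aborts with partial trace attached
  boom <- function(nid, st) if (nid == "B") stop("kaput")
  err <- tryCatch(run_schedule(sched_fixture(3), NULL, boom,
                               max_passes = 2),
                  error = function(e) e)
  expect_s3_class(err, "mdf_execution_error")
  expect_equal(err$trace$node, "A")
})

test_that("traces equal the brute-force replay oracle on randomized condition sets", {
  set.seed(23)
  for (nm in fixture_names()) {
    m <- flatten_hierarchy(make_fixture(nm))
    g <- m$graphs[[1]]
    ids <- graph_node_ids(m)
    for (rep in 1:10) {
      conds <- list()
      for (nid in ids)
        if (stats::runif(1) < 0.7)
          conds[[nid]] <- random_condition(ids)
      term <- if (stats::runif(1) < 0.5) cond_never()
              else cond_after_n_calls(sample(ids, 1), sample(2:5, 1))
      cs <- mdf_condition_set(node_specific = conds, termination = term)
      got <- run_schedule(g, cs, null_exec, max_passes = 8)
      want <- replay_schedule(ids, graph_edge_list(m),
                              lapply(conds, cond_as_list),
                              cond_as_list(term), max_passes = 8)
      expect_equal(got$trace$node, want$trace$node,
                   label = paste(nm, rep))
      expect_equal(got$trace$pass, want$trace$pass)
      expect_equal(got$outcome, want$outcome)
    }
  }
})

test_that("a node gated every_n executes exactly floor(calls(dep)/n) times", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    g <- sched_fixture(2, chain = FALSE)
    cs <- mdf_condition_set(
      node_specific = list(B = cond_every_n_calls("A", n)),
      termination = cond_never())
    passes <- sample(3:12, 1)
    res <- run_schedule(g, cs, null_exec, max_passes = passes)
    calls_A <- sum(res$trace$node == "A")
    expect_equal(sum(res$trace$node == "B"), calls_A %/% n)
  }
})

test_that("identical inputs give identical traces (determinism)", {
  m <- make_fixture("condition_demo")
  r1 <- run_model(m, max_passes = 50)
  r2 <- run_model(m, max_passes = 50)
  expect_identical(r1$trace, r2$trace)
})
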