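test_that("well-formed and degenerate models validate as expected", {
  empty <- mdf_model("m", graphs = list(mdf_graph("g")))
  expect_equal(nrow(validate_model(empty)), 0)

  # dangling edge endpoint
  bad <- mdf_model("m", graphs = list(mdf_graph("g",
    nodes = list(mdf_node("A",
      output_ports = list(mdf_output_port("out", "1")))),
    edges = list(mdf_edge("e", "A", "out", "X", "in1")))))
  rep <- validate_model(bad)
  expect_true(has_errors(rep))
  expect_equal(sum(grepl("'X' does not exist", rep$message)), 1)

  # validation is pure and idempotent
  expect_identical(validate_model(bad), validate_model(bad))
})

test_that("cycles are info-level when initialized, error-level otherwise", {
  cyc <- make_fixture("cyclic_pair")
  rep <- validate_model(cyc)
  expect_false(has_errors(rep))
  expect_equal(sum(rep$severity == "info" &
                     grepl("cycle detected", rep$message)), 1)

  # removing the initial values turns the cycle into an error
  cyc$graphs[[1]]$nodes[[1]]$output_ports[[1]]$default_initial_value <- NULL
  rep2 <- validate_model(cyc)
  expect_true(has_errors(rep2))
  expect_true(any(grepl("feeds a cycle", rep2$message)))
})

test_that("fan-in must be declared, duplicate ids and bad expressions are caught", {
  two_in <- function(reduce) mdf_model("m", graphs = list(mdf_graph("g",
    nodes = list(
      mdf_node("A", output_ports = list(mdf_output_port("out", "1"))),
      mdf_node("B", output_ports = list(mdf_output_port("out", "2"))),
      mdf_node("C",
        input_ports = list(mdf_input_port("in1", reduce = reduce)),
        output_ports = list(mdf_output_port("out", "in1")))),
    edges = list(mdf_edge("e1", "A", "out", "C", "in1"),
                 mdf_edge("e2", "B", "out", "C", "in1")))))
  expect_true(has_errors(validate_model(two_in("error"))))
  expect_false(has_errors(validate_model(two_in("sum"))))

  dup <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A", parameters = list(mdf_parameter("p", value = 1),
                                    mdf_parameter("p", value = 2)),
             output_ports = list(mdf_output_port("out", "p")))))))
  expect_true(any(grepl("duplicate component id 'p'",
                        validate_model(dup)$message)))

  badexpr <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A", output_ports = list(mdf_output_port("out", "1 +")))))))
  expect_true(any(grepl("does not parse", validate_model(badexpr)$message)))

  # output port referencing an id not defined in the node
  badref <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A", output_ports = list(mdf_output_port("out", "ghost")))))))
  expect_true(any(grepl("'ghost'", validate_model(badref)$message)))
})

test_that("statefulness rules: initial values required, non-stateful cycles rejected", {
  nostart <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A", parameters = list(mdf_parameter("c", value = "c + 1")),
             output_ports = list(mdf_output_port("out", "c")))))))
  expect_true(any(grepl("requires default_initial_value",
                        validate_model(nostart)$message)))

  mutual <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A",
      parameters = list(mdf_parameter("p", value = "q + 1"),
                        mdf_parameter("q", value = "p + 1")),
      output_ports = list(mdf_output_port("out", "p")))))))
  expect_true(any(grepl("intra-node cycle among non-stateful",
                        validate_model(mutual)$message)))

  # unknown function and missing required argument
  badfn <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A",
      functions = list(mdf_function_call("f", "conv2d", list())),
      output_ports = list(mdf_output_port("out", "f")))))))
  expect_true(any(grepl("unregistered function 'conv2d'",
                        validate_model(badfn)$message)))
  noarg <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A",
      functions = list(mdf_function_call("f", "relu", list())),
      output_ports = list(mdf_output_port("out", "f")))))))
  expect_true(any(grepl("misses required argument 'x'",
                        validate_model(noarg)$message)))
})

test_that("elementary circuits are enumerated completely and deterministically", {
  chain <- mdf_model("m", graphs = list(mdf_graph("g",
    nodes = list(
      mdf_node("A", output_ports = list(mdf_output_port("o", "1"))),
      mdf_node("B", input_ports = list(mdf_input_port("i")),
               output_ports = list(mdf_output_port("o", "i"))),
      mdf_node("C", input_ports = list(mdf_input_port("i")),
               output_ports = list(mdf_output_port("o", "i")))),
    edges = list(mdf_edge("e1", "A", "o", "B", "i"),
                 mdf_edge("e2", "B", "o", "C", "i")))))
  expect_equal(detect_cycles(chain$graphs[[1]]), list())

  expect_equal(detect_cycles(make_fixture("cyclic_pair")$graphs[[1]]),
               list(c("A", "B")))

  # complete digraph on 3 nodes: brute-force count of elementary
  # circuits is 5 (three 2-cycles, two 3-cycles)
  mknode <- function(id) mdf_node(id,
    input_ports = list(mdf_input_port("i", reduce = "sum")),
    output_ports = list(mdf_output_port("o", "i",
                                        default_initial_value = 0)))
  ids <- c("A", "B", "C")
  edges <- list()
  for (s in ids) for (r in setdiff(ids, s))
    edges[[length(edges) + 1L]] <- mdf_edge(paste0("e", s, r), s, "o",
                                            r, "i")
  k3 <- mdf_graph("g", nodes = lapply(ids, mknode), edges = edges)
  cycles <- detect_cycles(k3)
  expect_length(cycles, 5)
  # brute-force oracle: test every rotation-normalized candidate cycle
  cand <- c(lapply(utils::combn(ids, 2, simplify = FALSE), identity),
            list(c("A", "B", "C"), c("A", "C", "B")))
  present <- Filter(function(cy) {
    ok <- TRUE
    for (i in seq_along(cy)) {
      s <- cy[i]
      r <- cy[if (i == length(cy)) 1 else i + 1]
      ok <- ok && any(vapply(edges, function(e)
        e$sender == s && e$receiver == r, logical(1)))
    }
    ok
  }, cand)
  expect_equal(length(present), 5)
  key <- function(l) sort(vapply(l, paste, "", collapse = ">"))
  expect_equal(key(cycles), key(present))
  # determinism
  expect_identical(detect_cycles(k3), detect_cycles(k3))
})

test_that("flattening namespaces children, rewires boundaries, and is idempotent", {
  m <- make_fixture("nested_model")
  fl <- flatten_hierarchy(m)
  ids <- vapply(fl$graphs[[1]]$nodes, `[[`, "", "id")
  expect_setequal(ids, c("src", "wrap.Q", "wrap.R", "sink"))
  expect_false(any(vapply(fl$graphs[[1]]$nodes,
                          function(n) !is.null(n$subgraph), logical(1))))
  expect_equal(nrow(validate_model(fl)[validate_model(fl)$severity ==
                                         "error", ]), 0)
  # idempotence
  expect_true(models_equal(flatten_hierarchy(fl), fl))
  # identity on subgraph-free models
  ffn <- make_fixture("ffn_abc")
  expect_true(models_equal(flatten_hierarchy(ffn), ffn))

  # engine equivalence, including two-level nesting
  r1 <- run_model(m, max_passes = 1)$final_values$sink$out
  r2 <- run_model(fl, max_passes = 1)$final_values$sink$out
  expect_identical(r1, r2)
  expect_equal(r1, 35)

  inner1 <- mdf_graph("i1", nodes = list(
    mdf_node("Q", input_ports = list(mdf_input_port("in1")),
             output_ports = list(mdf_output_port("qout", "in1 + 10")))))
  W1 <- mdf_node("W1", input_ports = list(mdf_input_port("in1")),
                 output_ports = list(mdf_output_port("qout", "qout")),
                 subgraph = inner1)
  inner2 <- mdf_graph("i2", nodes = list(W1))
  W2 <- mdf_node("W2", input_ports = list(mdf_input_port("in1")),
                 output_ports = list(mdf_output_port("qout", "qout")),
                 subgraph = inner2)
  outer <- mdf_model("deep", graphs = list(mdf_graph("main",
    nodes = list(
      mdf_node("src",
        parameters = list(mdf_parameter("x", value = 2)),
        output_ports = list(mdf_output_port("out", "x"))),
      W2,
      mdf_node("sink",
        input_ports = list(mdf_input_port("in1")),
        output_ports = list(mdf_output_port("out", "in1 - 1")))),
    edges = list(mdf_edge("sw", "src", "out", "W2", "in1"),
                 mdf_edge("ws", "W2", "qout", "sink", "in1")))))
  fl2 <- flatten_hierarchy(outer)
  ids2 <- vapply(fl2$graphs[[1]]$nodes, `[[`, "", "id")
  expect_true("W2.W1.Q" %in% ids2)
  ra <- run_model(outer, max_passes = 1)$final_values
  rb <- run_model(fl2, max_passes = 1)$final_values
  expect_identical(ra$sink$out, rb$sink$out)
  expect_equal(ra$sink$out, 11)
})
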