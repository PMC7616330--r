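# reference engine: node evaluation, value propagation, Euler integration

test_that("node evaluation follows intra-node dependency order", {
  nd <- mdf_node("n",
    input_ports = list(mdf_input_port("in1")),
    parameters = list(mdf_parameter("p", value = "2*in1")),
    output_ports = list(mdf_output_port("out", "p + 1")))
  out <- evaluate_node(nd, list(in1 = 3))
  expect_equal(out$out, 7)

  # declaration order must not matter, only dependencies
  nd2 <- mdf_node("n",
    parameters = list(mdf_parameter("a", value = "b + 1"),
                      mdf_parameter("b", value = 2)),
    output_ports = list(mdf_output_port("out", "a * b")))
  expect_equal(evaluate_node(nd2)$out, 6)

  # mutual non-stateful reference is an error
  nd3 <- mdf_node("n",
    parameters = list(mdf_parameter("p", value = "q + 1"),
                      mdf_parameter("q", value = "p + 1")),
    output_ports = list(mdf_output_port("out", "p")))
  expect_error(evaluate_node(nd3), "intra-node cycle")
})

test_that("self-referencing parameters act as per-execution counters", {
  m <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A",
      parameters = list(mdf_parameter("c", value = "c + 1",
                                      default_initial_value = 0)),
      output_ports = list(mdf_output_port("out", "c")))),
    conditions = mdf_condition_set(termination = cond_never()))))
  res <- run_model(m, max_passes = 3, record = "A/c")
  expect_equal(unlist(res$recorded[["A/c"]]$values), c(1, 2, 3))
})

test_that("stateless feedforward composition evaluates in one pass", {
  res <- run_model(make_fixture("ffn_abc"), max_passes = 1)
  expect_equal(res$final_values$A$out, 5)
  expect_equal(res$final_values$B$out, 10)
  expect_equal(res$final_values$C$out, 7)
  expect_equal(res$outcome, "terminated")
  expect_equal(nrow(res$trace), 3)

  # single-pass topological evaluation oracle: direct arithmetic
  x <- 11
  res2 <- run_model(make_fixture("ffn_abc", x = x), max_passes = 1)
  expect_identical(res2$final_values$C$out, ((x + 1) * 2) - 3)
})

test_that("unconnected input ports read zero and count a warning", {
  m <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A",
      input_ports = list(mdf_input_port("in1")),
      output_ports = list(mdf_output_port("out", "in1 + 5")))))))
  res <- run_model(m, max_passes = 1)
  expect_equal(res$final_values$A$out, 5)
  expect_equal(res$warnings[["unconnected_input:A.in1"]], 1)
})

test_that("edge weights scale linear outputs linearly; fan-in sums", {
  mk <- function(w) mdf_model("m", graphs = list(mdf_graph("g",
    nodes = list(
      mdf_node("A", parameters = list(mdf_parameter("x", value = 3)),
               output_ports = list(mdf_output_port("out", "x"))),
      mdf_node("B", input_ports = list(mdf_input_port("in1")),
               output_ports = list(mdf_output_port("out", "in1 * 2")))),
    edges = list(mdf_edge("e", "A", "out", "B", "in1", weight = w)))))
  base <- run_model(mk(NULL), max_passes = 1)$final_values$B$out
  for (k in c(2, -0.5, 10)) {
    scaled <- run_model(mk(k), max_passes = 1)$final_values$B$out
    expect_equal(scaled, k * base)
  }

  fan <- mdf_model("m", graphs = list(mdf_graph("g",
    nodes = list(
      mdf_node("A", parameters = list(mdf_parameter("x", value = 3)),
               output_ports = list(mdf_output_port("out", "x"))),
      mdf_node("B", parameters = list(mdf_parameter("y", value = 4)),
               output_ports = list(mdf_output_port("out", "y"))),
      mdf_node("C",
        input_ports = list(mdf_input_port("in1", reduce = "sum")),
        output_ports = list(mdf_output_port("out", "in1")))),
    edges = list(mdf_edge("e1", "A", "out", "C", "in1"),
                 mdf_edge("e2", "B", "out", "C", "in1", weight = 10)))))
  expect_equal(run_model(fan, max_passes = 1)$final_values$C$out, 43)
})

test_that("cyclic edges read previous-pass committed values", {
  m <- make_fixture("cyclic_pair")
  m$graphs[[1]]$conditions <- mdf_condition_set(termination = cond_never())
  # A.out starts 0; pass k: A reads B's previous out
  res <- run_model(m, max_passes = 3, graph_id = "main")
  # pass0: A: 0+1=1, B: 1*2=2; pass1: A: 2+1=3, B: 6; pass2: A 7, B 14
  expect_equal(res$final_values$A$out, 7)
  expect_equal(res$final_values$B$out, 14)
})

test_that("forward Euler integrates dv/dt = -v with order-1 convergence", {
  decay <- function(dt, duration) {
    m <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
      mdf_node("A",
        parameters = list(mdf_parameter("v", default_initial_value = 1,
                                        time_derivative = "-v")),
        output_ports = list(mdf_output_port("out", "v")))))))
    run_model(m, dt = dt, duration = duration)$final_values$A$v
  }
  # one explicit step
  expect_equal(decay(0.1, 0.1), 0.9)
  # closed-form solution of the linear ODE as oracle
  expect_lt(abs(decay(1e-4, 1) - exp(-1)), 1e-3)
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(dt)
    abs(decay(dt, 1) - exp(-1)), 0)
  r1 <- errs[2] / errs[1]
  r2 <- errs[3] / errs[2]
  expect_gt(r1, 0.4); expect_lt(r1, 0.6)
  expect_gt(r2, 0.4); expect_lt(r2, 0.6)
})

test_that("FHN node matches an adaptive ODE oracle and oscillates under drive", {
  skip_if_not_installed("deSolve")
  m <- make_fixture("fhn_neuron", I_ext = 0.5)
  res <- run_model(m, dt = 0.01, duration = 30,
                   record = c("fhn/V", "fhn/W"))
  tV <- res$recorded[["fhn/V"]]
  V <- unlist(tV$values)
  W <- unlist(res$recorded[["fhn/W"]]$values)

  ref <- deSolve::ode(
    c(V = -1, W = -1), c(0, tV$clock),
    function(t, y, p) list(c(y[1] - y[1]^3 / 3 - y[2] + 0.5,
                             (y[1] + 0.7 - 0.8 * y[2]) / 12.5)),
    NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(V - ref[-1, "V"])), 0.05)
  expect_lt(max(abs(W - ref[-1, "W"])), 0.05)
  # relaxation oscillation: V leaves and re-enters the suprathreshold band
  expect_gt(max(V), 1.5)
  expect_lt(min(V), -1.5)
})

test_that("quiescent FHN settles at the root-found equilibrium", {
  m <- make_fixture("fhn_neuron", I_ext = 0)
  res <- run_model(m, dt = 0.01, duration = 150)
  g <- function(V) V - V^3 / 3 - (V + 0.7) / 0.8
  Vstar <- stats::uniroot(g, c(-3, 3), tol = 1e-14)$root
  expect_lt(abs(res$final_values$fhn$V - Vstar), 1e-3)
  expect_lt(abs(res$final_values$fhn$W - (Vstar + 0.7) / 0.8), 1e-3)
})

test_that("noise-free drift-diffusion run is an exact ramp; seeds reproduce bits", {
  m <- make_fixture("ddm_accumulator", drift_rate = 1, noise_coeff = 0)
  res <- run_model(m, dt = 0.1, duration = 1, seed = 5, record = "ddm/x")
  expect_equal(unlist(res$recorded[["ddm/x"]]$values),
               seq(0.1, 1, by = 0.1))

  m2 <- make_fixture("ddm_accumulator")
  ra <- run_model(m2, dt = 0.1, duration = 1, seed = 77, record = "ddm/x")
  rb <- run_model(m2, dt = 0.1, duration = 1, seed = 77, record = "ddm/x")
  expect_identical(ra$recorded, rb$recorded)
  expect_identical(ra$trace, rb$trace)
  rc <- run_model(m2, dt = 0.1, duration = 1, seed = 78, record = "ddm/x")
  expect_false(identical(ra$recorded, rc$recorded))
})

test_that("vectorized DDM ensemble matches Brownian-motion moments", {
  n <- 10000
  m <- make_fixture("ddm_accumulator", drift_rate = 0.5, noise_coeff = 1,
                    n_paths = n)
  res <- run_model(m, dt = 0.1, duration = 1, seed = 99)
  x <- res$final_values$ddm$x
  expect_length(x, n)
  expect_lt(abs(mean(x) - 0.5), 3 / sqrt(n))
  expect_lt(abs(stats::var(x) - 1.0), 3 * sqrt(2 / (n - 1)))
})

test_that("non-finite values raise once past the configured limit", {
  m <- mdf_model("m", graphs = list(mdf_graph("g", nodes = list(
    mdf_node("A",
      parameters = list(mdf_parameter("v", default_initial_value = 1,
                                      time_derivative = "v * v * 1e6")),
      output_ports = list(mdf_output_port("out", "v")))))))
  expect_error(run_model(m, dt = 10, duration = 1000,
                         nonfinite_limit = 3),
               "non-finite")
})

test_that("recorded CSV has a clock column and one column per slot", {
  dir <- withr::local_tempdir()
  res <- run_model(make_fixture("condition_demo"), max_passes = 50,
                   record = c("fast/count", "slow/count"))
  p <- file.path(dir, "rec.csv")
  write_recorded_csv(res, p)
  df <- utils::read.csv(p, check.names = FALSE)
  expect_equal(names(df), c("clock", "fast/count", "slow/count"))
  expect_equal(max(df$`fast/count`, na.rm = TRUE), 10)
  expect_equal(max(df$`slow/count`, na.rm = TRUE), 5)
})
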