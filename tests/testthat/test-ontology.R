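test_that("registry enforces uniqueness and resolves lookups", {
  reg <- function_registry()
  register_function(reg, "linear", function(x, m = 1, b = 0) m * x + b,
                    list(list(name = "x", required = TRUE, default = NULL),
                         list(name = "m", required = FALSE, default = 1),
                         list(name = "b", required = FALSE, default = 0)),
                    "elementwise", "m*x + b")
  def <- lookup_function(reg, "linear")
  expect_equal(def$name, "linear")
  expect_equal(def$doc, "m*x + b")
  expect_error(lookup_function(reg, "no_such_fn"), "unknown function")
  expect_error(register_function(reg, "linear", identity),
               "duplicate function name")
  expect_error(lookup_function(core_operator_set(), "conv2d"),
               "unknown function")
  expect_error(register_function(core_operator_set(), "relu", identity),
               "duplicate")
  # required args must precede optional ones
  expect_error(
    register_function(function_registry(), "bad", function(a, b) a,
                      list(list(name = "a", required = FALSE, default = 1),
                           list(name = "b", required = TRUE,
                                default = NULL))),
    "required args must precede")
})

test_that("core operators match naive loop oracles on random arrays", {
  reg <- core_operator_set()
  ev <- function(src, binds) evaluate_expression(src, binds, reg)
  set.seed(101)
  for (i in 1:25) {
    v <- stats::runif(sample(2:6, 1), -2, 2)
    w <- stats::runif(length(v), -2, 2)
    m <- matrix(stats::runif(6, -2, 2), 2, 3)
    p <- matrix(stats::runif(6, -2, 2), 3, 2)

    expect_close(ev("add(a, b)", list(a = v, b = w)),
                 oracle_binary(`+`)(v, w), 1e-10)
    expect_close(ev("sub(a, b)", list(a = v, b = w)),
                 oracle_binary(`-`)(v, w), 1e-10)
    expect_close(ev("mul(a, b)", list(a = v, b = w)),
                 oracle_binary(`*`)(v, w), 1e-10)
    expect_close(ev("div(a, b)", list(a = v, b = w + 3)),
                 oracle_binary(`/`)(v, w + 3), 1e-10)
    expect_close(ev("pow(a, b)", list(a = abs(v), b = w)),
                 oracle_binary(`^`)(abs(v), w), 1e-10)
    expect_close(ev("neg(a)", list(a = v)),
                 oracle_elementwise(function(x) -x)(v), 1e-10)
    expect_close(ev("abs(a)", list(a = v)), oracle_elementwise(abs)(v),
                 1e-10)
    expect_close(ev("exp(a)", list(a = v)), oracle_elementwise(exp)(v),
                 1e-10)
    expect_close(ev("log(a)", list(a = abs(v) + 0.1)),
                 oracle_elementwise(log)(abs(v) + 0.1), 1e-10)
    expect_close(ev("sqrt(a)", list(a = abs(v))),
                 oracle_elementwise(sqrt)(abs(v)), 1e-10)
    expect_close(ev("sin(a)", list(a = v)), oracle_elementwise(sin)(v),
                 1e-10)
    expect_close(ev("cos(a)", list(a = v)), oracle_elementwise(cos)(v),
                 1e-10)
    expect_close(ev("tanh(a)", list(a = v)), oracle_elementwise(tanh)(v),
                 1e-10)
    expect_close(ev("sigmoid(a)", list(a = v)),
                 oracle_elementwise(function(x) 1 / (1 + exp(-x)))(v),
                 1e-10)
    expect_close(ev("relu(a)", list(a = v)),
                 oracle_elementwise(function(x) max(x, 0))(v), 1e-10)
    expect_close(ev("softmax(a)", list(a = v)), oracle_softmax_vec(v),
                 1e-10)
    expect_close(ev("softmax(a)", list(a = m)), oracle_softmax(m), 1e-10)
    expect_close(ev("matmul(a, b)", list(a = m, b = p)),
                 oracle_matmul(m, p), 1e-10)
    expect_close(ev("matmul(a, b)", list(a = v, b = v)),
                 oracle_matmul(v, v), 1e-10)
    expect_close(ev("transpose(a)", list(a = m)), oracle_transpose(m),
                 1e-10)
    expect_close(ev("reduce_sum(a)", list(a = m)),
                 oracle_reduce(sum)(m), 1e-10)
    expect_close(ev("reduce_sum(a, 1)", list(a = m)),
                 oracle_reduce(sum)(m, 1), 1e-10)
    expect_close(ev("reduce_mean(a, 2)", list(a = m)),
                 oracle_reduce(mean)(m, 2), 1e-10)
    expect_close(ev("reduce_max(a)", list(a = v)),
                 oracle_reduce(max)(v), 1e-10)
    expect_close(ev("clip(a, 0 - 1, 1)", list(a = v)),
                 oracle_clip(v, -1, 1), 1e-10)
    expect_close(ev("concat(a, b)", list(a = v, b = w)), c(v, w), 1e-10)
    expect_close(ev("reshape(a, s)", list(a = m, s = c(3, 2))),
                 oracle_reshape_rowmajor(m, c(3, 2)), 1e-10)
  }
})

test_that("relu/softmax fixed points and matmul shape handling", {
  reg <- core_operator_set()
  expect_equal(evaluate_expression("relu(x)", list(x = c(-1, 0, 2)), reg),
               c(0, 0, 2))
  expect_equal(evaluate_expression("softmax(x)", list(x = c(0, 0)), reg),
               c(0.5, 0.5))
  m23 <- matrix(1:6, 2, 3, byrow = TRUE)
  m32 <- matrix(1:6, 3, 2, byrow = TRUE)
  got <- evaluate_expression("matmul(a, b)", list(a = m23, b = m32), reg)
  expect_equal(dim(got), c(2L, 2L))
  expect_equal(got, oracle_matmul(m23, m32))
})

test_that("elementwise operators commute with reshape; softmax normalizes", {
  reg <- core_operator_set()
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(stats::runif(12, -3, 3), 3, 4)
    f_then_r <- evaluate_expression("reshape(tanh(x), s)",
                                    list(x = m, s = c(4, 3)), reg)
    r_then_f <- evaluate_expression("tanh(reshape(x, s))",
                                    list(x = m, s = c(4, 3)), reg)
    expect_close(f_then_r, r_then_f, 1e-12)

    sm <- evaluate_expression("softmax(x)", list(x = m), reg)
    expect_true(all(sm >= 0))
    expect_close(rowSums(sm), rep(1, 3), 1e-12)
  }
})

test_that("FitzHugh-Nagumo derivatives match direct substitution and vanish at equilibrium", {
  d <- fhn_derivatives(0, 0, a = 0.7, b = 0.8, tau = 12.5, I_ext = 0)
  expect_equal(d$dV_dt, 0)
  expect_equal(d$dW_dt, 0.056)
  expect_equal(fhn_derivatives(1, 1, I_ext = 0.5)$dV_dt, 1 / 6)
  expect_error(fhn_derivatives(0, 0, tau = 0), "tau must be > 0")

  # equilibrium from a root-finding oracle on the two equations
  g <- function(V) V - V^3 / 3 - (V + 0.7) / 0.8
  Vstar <- stats::uniroot(g, c(-3, 3), tol = 1e-14)$root
  Wstar <- (Vstar + 0.7) / 0.8
  deq <- fhn_derivatives(Vstar, Wstar)
  expect_lt(abs(deq$dV_dt), 1e-9)
  expect_lt(abs(deq$dW_dt), 1e-9)
})

test_that("drift-diffusion step is exact in the deterministic limits and unbiased in ensemble", {
  expect_equal(ddm_step(0, 1, 0, 0.1, 42), 0.1)
  expect_equal(ddm_step(0, 0, 1, 0.25, 2), 1.0)
  expect_error(ddm_step(0, 1, 1, 0, 1), "dt must be > 0")

  # Monte-Carlo against the closed-form mean A*T and variance c^2*T
  set.seed(2024)
  n <- 10000
  x <- rep(0, n)
  dt <- 0.1
  for (k in 1:10) x <- ddm_step(x, 0.5, 1, dt, stats::rnorm(n))
  se_mean <- 1 / sqrt(n)
  expect_lt(abs(mean(x) - 0.5), 3 * se_mean)
  se_var <- 1 * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(x) - 1.0), 3 * se_var)
})

test_that("ontology catalog exports every registered function with its docs", {
  reg <- core_operator_set()
  cat_list <- ontology_catalog(reg)
  nms <- vapply(cat_list, `[[`, "", "name")
  expect_true(all(c("add", "relu", "softmax", "matmul", "reshape",
                    "fitzhugh_nagumo_dV", "drift_diffusion_step")
                  %in% nms))
  expect_gte(length(nms), 24)
  expect_true(all(vapply(cat_list, function(d) nzchar(d$doc), logical(1))))
  p <- withr::local_tempfile(fileext = ".json")
  ontology_catalog(reg, p)
  tree <- jsonlite::parse_json(readChar(p, file.info(p)$size))
  expect_equal(length(tree), length(nms))
})
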