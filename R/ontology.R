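# Function ontology: a registry of named, documented functions callable
# from expressions and FunctionCalls. The core set mirrors the ONNX
# definitions of the same-named operators on dense arrays; axis arguments
# are 1-based (R convention) and reshape/flatten order is row-major to
# match the ONNX data layout.

#' Create an empty function registry
#'
#' @return An object of class `mdf_registry`.
#' @seealso [core_operator_set()] for a preloaded registry.
#' @export
function_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "mdf_registry")
}

#' @export
print.mdf_registry <- function(x, ...) {
  cat("<function registry> ", length(ls(x$env)), " functions\n", sep = "")
  invisible(x)
}

#' Register a function definition
#'
#' @param registry An `mdf_registry`.
#' @param name Function name (unique within the registry).
#' @param fn R function implementing it; formals must match `args`.
#' @param args Ordered list of argument specs, each a list with `name`,
#'   `required` (logical) and `default`. Required arguments must precede
#'   optional ones.
#' @param arity_class One of `"elementwise"`, `"reduction"`,
#'   `"structural"`.
#' @param doc One-line documentation string (embedded in the exported
#'   catalog so serialized models are self-describing).
#' @return The registry, invisibly.
#' @export
register_function <- function(registry, name, fn,
                              args = list(),
                              arity_class = c("elementwise", "reduction",
                                              "structural"),
                              doc = "") {
  stopifnot(inherits(registry, "mdf_registry"), is.function(fn))
  arity_class <- match.arg(arity_class)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    stop(sprintf("invalid function name '%s'", name), call. = FALSE)
  if (exists(name, envir = registry$env, inherits = FALSE))
    stop(sprintf("duplicate function name '%s'", name), call. = FALSE)
  req <- vapply(args, function(a) isTRUE(a$required), logical(1))
  if (length(req) > 1 && any(diff(!req) < 0))
    stop("required args must precede optional args", call. = FALSE)
  def <- structure(list(name = name, args = args, arity_class = arity_class,
                        fn = fn, doc = doc), class = "mdf_function_def")
  assign(name, def, envir = registry$env)
  invisible(registry)
}

#' Look up a function definition
#'
#' @param registry An `mdf_registry`.
#' @param name Function name.
#' @return The `mdf_function_def`.
#' @export
lookup_function <- function(registry, name) {
  stopifnot(inherits(registry, "mdf_registry"))
  if (!exists(name, envir = registry$env, inherits = FALSE))
    stop(sprintf("unknown function '%s'", name), call. = FALSE)
  get(name, envir = registry$env, inherits = FALSE)
}

#' List registered function names
#' @param registry An `mdf_registry`.
#' @return Sorted character vector.
#' @export
registry_names <- function(registry) sort(ls(registry$env))

# Apply a registered function to a list of evaluated arguments.
# `args` may be positional (unnamed), named, or mixed; defaults fill the
# rest and missing required arguments are an error.
apply_function <- function(registry, name, args) {
  def <- lookup_function(registry, name)
  spec_names <- vapply(def$args, `[[`, "", "name")
  supplied <- names(args)
  if (is.null(supplied)) supplied <- rep("", length(args))
  final <- list()
  pos <- 1L
  for (i in seq_along(args)) {
    nm <- supplied[i]
    if (nm == "") {
      if (pos > length(spec_names))
        stop(sprintf("too many arguments to '%s'", name), call. = FALSE)
      final[[spec_names[pos]]] <- args[[i]]
      pos <- pos + 1L
    } else {
      if (!(nm %in% spec_names))
        stop(sprintf("unknown argument '%s' to '%s'", nm, name),
             call. = FALSE)
      final[[nm]] <- args[[i]]
    }
  }
  for (a in def$args) {
    if (is.null(final[[a$name]])) {
      if (isTRUE(a$required))
        stop(sprintf("missing required argument '%s' to '%s'", a$name, name),
             call. = FALSE)
      final[[a$name]] <- a$default
    }
  }
  do.call(def$fn, final)
}

arg_req <- function(name) list(name = name, required = TRUE, default = NULL)
arg_opt <- function(name, default) list(name = name, required = FALSE,
                                        default = default)

# row-major (C-order) flatten / unflatten, matching ONNX data layout
flatten_rowmajor <- function(x) {
  if (is.null(dim(x))) return(as.numeric(x))
  as.numeric(aperm(x, rev(seq_along(dim(x)))))
}

unflatten_rowmajor <- function(v, shape) {
  if (length(shape) <= 1L) return(as.numeric(v))
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

ew1 <- function(f) function(x) {
  r <- f(x)
  storage.mode(r) <- "double"
  dim(r) <- dim(x)
  r
}

op_softmax <- function(x, axis = NULL) {
  sm <- function(v) {
    e <- exp(v - max(v))
    e / sum(e)
  }
  if (is.null(dim(x))) return(sm(as.numeric(x)))
  d <- dim(x)
  if (length(d) != 2L)
    stop("softmax supports vectors and matrices", call. = FALSE)
  if (is.null(axis)) axis <- 2L
  axis <- as.integer(axis)
  if (!(axis %in% c(1L, 2L))) stop("softmax: axis must be 1 or 2",
                                   call. = FALSE)
  if (axis == 2L) t(apply(x, 1L, sm)) else apply(x, 2L, sm)
}

op_matmul <- function(a, b) {
  av <- is.null(dim(a))
  bv <- is.null(dim(b))
  if (av && bv) return(as.numeric(a %*% b))       # dot product -> scalar
  r <- (if (av) matrix(a, nrow = 1L) else a) %*%
       (if (bv) matrix(b, ncol = 1L) else b)
  if (av || bv) as.numeric(r) else r              # drop the promoted dim
}

op_transpose <- function(x, perm = NULL) {
  if (is.null(dim(x))) return(as.numeric(x))
  if (is.null(perm)) perm <- rev(seq_along(dim(x)))
  aperm(x, as.integer(perm))
}

op_reduce <- function(f) function(x, axes = NULL, keepdims = FALSE) {
  if (is.null(dim(x)) || is.null(axes)) {
    if (is.null(axes)) {
      r <- f(as.numeric(x))
      if (isTRUE(keepdims) && !is.null(dim(x))) {
        r <- array(r, dim = rep(1L, length(dim(x))))
      }
      return(r)
    }
    # vector with axes given: only axis 1 meaningful
    if (!all(as.integer(axes) == 1L)) stop("reduce: bad axes for a vector",
                                           call. = FALSE)
    return(f(as.numeric(x)))
  }
  d <- dim(x)
  axes <- as.integer(axes)
  if (any(axes < 1L | axes > length(d))) stop("reduce: axis out of range",
                                              call. = FALSE)
  keep <- setdiff(seq_along(d), axes)
  if (length(keep) == 0L) {
    r <- f(as.numeric(x))
    if (isTRUE(keepdims)) r <- array(r, dim = rep(1L, length(d)))
    return(r)
  }
  r <- apply(x, keep, f)
  if (isTRUE(keepdims)) {
    full <- d
    full[axes] <- 1L
    r <- unflatten_rowmajor(flatten_rowmajor(
      if (is.null(dim(r))) array(r, dim = d[keep]) else r), full)
    # note: reshaping a reduced array back with singleton axes preserves
    # element order because only size-1 axes are inserted
  } else if (length(keep) == 1L) {
    r <- as.numeric(r)
  }
  r
}

op_clip <- function(x, min = -Inf, max = Inf) {
  r <- pmin(pmax(as.numeric(x), as.numeric(min)[1]), as.numeric(max)[1])
  dim(r) <- dim(x)
  r
}

op_concat <- function(a, b, axis = 1) {
  axis <- as.integer(axis)
  if (is.null(dim(a)) && is.null(dim(b))) {
    if (axis != 1L) stop("concat: vectors concatenate along axis 1",
                         call. = FALSE)
    return(c(as.numeric(a), as.numeric(b)))
  }
  if (is.null(dim(a)) || is.null(dim(b)) ||
      length(dim(a)) != 2L || length(dim(b)) != 2L)
    stop("concat: operands must both be vectors or both matrices",
         call. = FALSE)
  if (axis == 1L) rbind(a, b)
  else if (axis == 2L) cbind(a, b)
  else stop("concat: axis must be 1 or 2", call. = FALSE)
}

op_reshape <- function(x, shape) {
  shape <- as.numeric(shape)
  v <- flatten_rowmajor(x)
  if (any(shape == -1)) {
    if (sum(shape == -1) > 1L) stop("reshape: at most one -1 in shape",
                                    call. = FALSE)
    known <- prod(shape[shape != -1])
    shape[shape == -1] <- length(v) / known
  }
  if (prod(shape) != length(v))
    stop(sprintf("reshape: cannot reshape %d elements to shape %s",
                 length(v), paste(shape, collapse = "x")), call. = FALSE)
  unflatten_rowmajor(v, as.integer(shape))
}

#' FitzHugh-Nagumo derivatives
#'
#' Right-hand side of the two-variable FitzHugh-Nagumo reduced neuron
#' model in its standard form
#' \deqn{dV/dt = V - V^3/3 - W + I_{ext}}
#' \deqn{dW/dt = (V + a - b W)/\tau}
#' where `V` is the fast (voltage-like) variable, `W` the slow recovery
#' variable, and `I_ext` the external drive. With the canonical
#' parameters a = 0.7, b = 0.8, tau = 12.5 the model is quiescent at
#' I_ext = 0 and produces sustained relaxation oscillations at
#' suprathreshold drive such as I_ext = 0.5.
#'
#' @param V,W State (scalar or array; elementwise).
#' @param a,b,tau Recovery-variable parameters; `tau` (> 0) is the
#'   recovery time constant in model time units.
#' @param I_ext External input current.
#' @return List with components `dV_dt` and `dW_dt`.
#' @export
fhn_derivatives <- function(V, W, a = 0.7, b = 0.8, tau = 12.5, I_ext = 0) {
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  list(dV_dt = V - V^3 / 3 - W + I_ext,
       dW_dt = (V + a - b * W) / tau)
}

#' One Euler-Maruyama step of a drift-diffusion accumulator
#'
#' Advances the accumulator `x` by
#' \deqn{x' = x + A\,dt + c\,\sqrt{dt}\,\xi}
#' with drift rate `A = drift_rate`, diffusion coefficient
#' `c = noise_coeff`, and `noise_sample` a standard-normal draw injected
#' by the caller, keeping the step itself deterministic and testable. The
#' engine owns the seeded generator.
#'
#' @param x Current accumulator value (scalar or array).
#' @param drift_rate Deterministic drift per unit time.
#' @param noise_coeff Diffusion coefficient.
#' @param dt Step size (> 0), model time units.
#' @param noise_sample Standard-normal draw(s), broadcast against `x`.
#' @return Updated accumulator value.
#' @export
ddm_step <- function(x, drift_rate, noise_coeff, dt, noise_sample) {
  if (any(dt <= 0)) stop("dt must be > 0", call. = FALSE)
  x + drift_rate * dt + noise_coeff * sqrt(dt) * noise_sample
}

#' Core operator registry
#'
#' A registry preloaded with a 24-operator core tensor set matching the
#' ONNX definitions of the same names on dense arrays (`add`, `sub`,
#' `mul`, `div`, `pow`, `neg`, `abs`, `exp`, `log`, `sqrt`, `sin`, `cos`,
#' `tanh`, `sigmoid`, `relu`, `softmax`, `matmul`, `transpose`,
#' `reduce_sum`, `reduce_mean`, `reduce_max`, `clip`, `concat`,
#' `reshape`), plus domain integrators: the FitzHugh-Nagumo right-hand
#' sides (`fitzhugh_nagumo_dV`, `fitzhugh_nagumo_dW`), the
#' drift-diffusion Euler-Maruyama step (`drift_diffusion_step`) and a
#' seeded standard-normal source (`random_standard_normal`). The registry
#' is extensible via [register_function()]; the full non-conditional
#' ONNX operator set is reachable through that extension mechanism.
#'
#' Axis arguments are 1-based; `reshape` uses row-major element order.
#'
#' @return An `mdf_registry`.
#' @examples
#' reg <- core_operator_set()
#' evaluate_expression("relu(x)", list(x = c(-1, 0, 2)), reg)
#' @export
core_operator_set <- function() {
  reg <- function_registry()
  bin <- function(op, f, doc) {
    register_function(reg, op, function(a, b) expr_broadcast2(op, a, b, f),
                      list(arg_req("a"), arg_req("b")), "elementwise", doc)
  }
  bin("add", `+`, "Elementwise addition a + b.")
  bin("sub", `-`, "Elementwise subtraction a - b.")
  bin("mul", `*`, "Elementwise multiplication a * b.")
  bin("div", `/`, "Elementwise division a / b (IEEE semantics).")
  bin("pow", `^`, "Elementwise power a ** b.")
  un <- function(op, f, doc) {
    register_function(reg, op, ew1(f), list(arg_req("x")), "elementwise", doc)
  }
  un("neg", function(x) -x, "Elementwise negation.")
  un("abs", abs, "Elementwise absolute value.")
  un("exp", exp, "Elementwise exponential.")
  un("log", log, "Elementwise natural logarithm.")
  un("sqrt", sqrt, "Elementwise square root.")
  un("sin", sin, "Elementwise sine.")
  un("cos", cos, "Elementwise cosine.")
  un("tanh", tanh, "Elementwise hyperbolic tangent.")
  un("sigmoid", function(x) 1 / (1 + exp(-x)), "Elementwise logistic sigmoid.")
  un("relu", function(x) pmax(x, 0), "Elementwise rectified linear unit.")
  register_function(reg, "softmax", op_softmax,
                    list(arg_req("x"), arg_opt("axis", NULL)), "reduction",
                    "Softmax along an axis (default: last); outputs are nonnegative and sum to 1 along that axis.")
  register_function(reg, "matmul", op_matmul,
                    list(arg_req("a"), arg_req("b")), "structural",
                    "Matrix product; 1-D operands are promoted as in ONNX MatMul and the promoted axis dropped.")
  register_function(reg, "transpose", op_transpose,
                    list(arg_req("x"), arg_opt("perm", NULL)), "structural",
                    "Axis permutation (default: reverse all axes).")
  register_function(reg, "reduce_sum", op_reduce(sum),
                    list(arg_req("x"), arg_opt("axes", NULL),
                         arg_opt("keepdims", FALSE)), "reduction",
                    "Sum over the given 1-based axes (default: all).")
  register_function(reg, "reduce_mean", op_reduce(mean),
                    list(arg_req("x"), arg_opt("axes", NULL),
                         arg_opt("keepdims", FALSE)), "reduction",
                    "Mean over the given 1-based axes (default: all).")
  register_function(reg, "reduce_max", op_reduce(max),
                    list(arg_req("x"), arg_opt("axes", NULL),
                         arg_opt("keepdims", FALSE)), "reduction",
                    "Maximum over the given 1-based axes (default: all).")
  register_function(reg, "clip", op_clip,
                    list(arg_req("x"), arg_opt("min", -Inf),
                         arg_opt("max", Inf)), "elementwise",
                    "Clamp values to [min, max].")
  register_function(reg, "concat", op_concat,
                    list(arg_req("a"), arg_req("b"), arg_opt("axis", 1)),
                    "structural",
                    "Concatenate two vectors or matrices along a 1-based axis.")
  register_function(reg, "reshape", op_reshape,
                    list(arg_req("x"), arg_req("shape")), "structural",
                    "Reshape to the given shape (row-major order; one -1 entry is inferred).")
  register_function(reg, "fitzhugh_nagumo_dV",
                    function(V, W, I_ext) fhn_derivatives(V, W, I_ext = I_ext)$dV_dt,
                    list(arg_req("V"), arg_req("W"), arg_opt("I_ext", 0)),
                    "elementwise",
                    "FitzHugh-Nagumo voltage derivative: V - V**3/3 - W + I_ext.")
  register_function(reg, "fitzhugh_nagumo_dW",
                    function(V, W, a, b, tau)
                      fhn_derivatives(V, W, a = a, b = b, tau = tau)$dW_dt,
                    list(arg_req("V"), arg_req("W"), arg_opt("a", 0.7),
                         arg_opt("b", 0.8), arg_opt("tau", 12.5)),
                    "elementwise",
                    "FitzHugh-Nagumo recovery derivative: (V + a - b*W)/tau.")
  register_function(reg, "drift_diffusion_step", ddm_step,
                    list(arg_req("x"), arg_req("drift_rate"),
                         arg_req("noise_coeff"), arg_req("dt"),
                         arg_req("noise_sample")), "elementwise",
                    "One Euler-Maruyama step: x + drift_rate*dt + noise_coeff*sqrt(dt)*noise_sample.")
  register_function(reg, "random_standard_normal",
                    function(n = 1) stats::rnorm(as.integer(n)),
                    list(arg_opt("n", 1)), "structural",
                    "n independent standard-normal draws from the run-level seeded generator.")
  reg
}

#' Machine-readable ontology catalog
#'
#' Exports the registry as a catalog (name, arguments, arity class, doc)
#' suitable for serialization to JSON.
#'
#' @param registry An `mdf_registry`.
#' @param path Optional file path; when given, the catalog is written as
#'   JSON and the path returned invisibly.
#' @return A list (one entry per function, sorted by name), or the path.
#' @export
ontology_catalog <- function(registry, path = NULL) {
  cat_list <- lapply(registry_names(registry), function(nm) {
    d <- lookup_function(registry, nm)
    list(name = nm,
         args = lapply(d$args, function(a)
           list(name = a$name, required = isTRUE(a$required))),
         arity_class = d$arity_class,
         doc = d$doc)
  })
  if (is.null(path)) return(cat_list)
  writeLines(jsonlite::toJSON(cat_list, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}
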