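# Expression language: the arithmetic strings used in parameter values,
# function-call arguments and output ports.
#
# Grammar (operators in increasing precedence):
#   comparison   <  <=  >  >=  ==  !=     (yield 0/1)
#   additive     +  -
#   multiplic.   *  /  %
#   unary        -x
#   power        **                       (right-associative, binds tighter
#                                          than unary minus: -2**2 == -4)
#   postfix      f(a, b)   x[i]
# Atoms: numbers (int/float/scientific), identifiers [A-Za-z_][A-Za-z0-9_]*,
# parenthesised expressions. Indexing is 1-based (R convention) and linear
# over the storage of an array.

#' Parse an expression string
#'
#' Parses an arithmetic expression into an abstract syntax tree. The
#' grammar covers numbers, identifiers, `+ - * / %` and `**` (power,
#' right-associative), unary minus, comparisons (`< <= > >= == !=`,
#' evaluating to 0/1), parentheses, call syntax `f(a, b)` and 1-based
#' element indexing `x[i]`. Unary minus binds looser than `**`, so
#' `-2**2` evaluates to -4.
#'
#' @param source A single character string.
#' @return An object of class `mdf_expression` with fields `source` and
#'   `ast`.
#' @examples
#' e <- parse_expression("a + b*2")
#' evaluate_expression(e, list(a = 1, b = 2))
#' @export
parse_expression <- function(source) {
  if (inherits(source, "mdf_expression")) return(source)
  if (is.numeric(source) && length(source) == 1L) {
    return(structure(list(source = format(source), ast = expr_num(source)),
                     class = "mdf_expression"))
  }
  stopifnot(is.character(source), length(source) == 1L)
  cached <- .expr_cache[[source]]
  if (!is.null(cached)) return(cached)
  toks <- expr_tokenize(source)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  ast <- expr_parse_bp(st, 0L)
  tk <- expr_peek(st)
  if (tk$type != "eof") {
    expr_syntax_error(sprintf("unexpected '%s'", tk$text), tk$pos)
  }
  out <- structure(list(source = source, ast = ast),
                   class = "mdf_expression")
  .expr_cache[[source]] <- out
  out
}

# parsing is pure, so parsed ASTs are memoized by source string
.expr_cache <- new.env(parent = emptyenv())

#' @export
print.mdf_expression <- function(x, ...) {
  cat("<expression> ", x$source, "\n", sep = "")
  invisible(x)
}

expr_num <- function(v) list(kind = "num", value = as.numeric(v))
expr_id <- function(nm) list(kind = "id", name = nm)

# offset is reported 0-based
expr_syntax_error <- function(msg, pos) {
  stop(structure(class = c("mdf_syntax_error", "error", "condition"),
                 list(message = sprintf("syntax error at offset %d: %s",
                                        pos - 1L, msg),
                      call = NULL, offset = pos - 1L)))
}

expr_tokenize <- function(src) {
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  two_char <- c("**", "<=", ">=", "==", "!=")
  singles <- c("+", "-", "*", "/", "%", "<", ">", "(", ")", "[", "]", ",")
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    start <- i
    if (grepl("^[0-9.]$", ch)) {
      if (ch == "." && (i == n || !grepl("^[0-9]$", chars[i + 1L])))
        expr_syntax_error("unexpected '.'", i)
      j <- i
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      if (j <= n && chars[j] == ".") {
        j <- j + 1L
        while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      }
      if (j <= n && chars[j] %in% c("e", "E")) {
        k <- j + 1L
        if (k <= n && chars[k] %in% c("+", "-")) k <- k + 1L
        if (k > n || !grepl("^[0-9]$", chars[k]))
          expr_syntax_error("malformed exponent", j)
        j <- k
        while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      }
      txt <- paste(chars[start:(j - 1L)], collapse = "")
      toks[[length(toks) + 1L]] <- list(type = "num", text = txt, pos = start)
      i <- j
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", chars[j])) j <- j + 1L
      txt <- paste(chars[start:(j - 1L)], collapse = "")
      toks[[length(toks) + 1L]] <- list(type = "id", text = txt, pos = start)
      i <- j
      next
    }
    pair <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (pair %in% two_char) {
      toks[[length(toks) + 1L]] <- list(type = "op", text = pair, pos = start)
      i <- i + 2L
      next
    }
    if (ch %in% singles) {
      toks[[length(toks) + 1L]] <- list(type = "op", text = ch, pos = start)
      i <- i + 1L
      next
    }
    expr_syntax_error(sprintf("unexpected character '%s'", ch), i)
  }
  toks[[length(toks) + 1L]] <- list(type = "eof", text = "", pos = n + 1L)
  toks
}

expr_peek <- function(st) st$toks[[st$i]]
expr_next <- function(st) {
  tk <- st$toks[[st$i]]
  st$i <- st$i + 1L
  tk
}
expr_expect <- function(st, text) {
  tk <- expr_next(st)
  if (tk$type == "eof" || tk$text != text)
    expr_syntax_error(sprintf("expected '%s'", text), tk$pos)
  tk
}

# left binding powers
EXPR_LBP <- c("<" = 10, "<=" = 10, ">" = 10, ">=" = 10, "==" = 10, "!=" = 10,
              "+" = 20, "-" = 20,
              "*" = 30, "/" = 30, "%" = 30,
              "**" = 50,
              "(" = 60, "[" = 60)
EXPR_UNARY_BP <- 40  # between * and ** so that -2**2 == -(2**2), -a*b == (-a)*b

expr_parse_bp <- function(st, min_bp) {
  tk <- expr_next(st)
  left <- switch(tk$type,
    num = expr_num(as.numeric(tk$text)),
    id = expr_id(tk$text),
    op = {
      if (tk$text == "-") {
        list(kind = "unary", op = "-", arg = expr_parse_bp(st, EXPR_UNARY_BP))
      } else if (tk$text == "(") {
        inner <- expr_parse_bp(st, 0L)
        expr_expect(st, ")")
        inner
      } else expr_syntax_error(sprintf("unexpected '%s'", tk$text), tk$pos)
    },
    eof = expr_syntax_error("incomplete expression", tk$pos),
    expr_syntax_error("unexpected token", tk$pos)
  )
  repeat {
    tk <- expr_peek(st)
    if (tk$type != "op") break
    bp <- EXPR_LBP[tk$text]
    if (is.na(bp) || bp <= min_bp) break
    expr_next(st)
    if (tk$text == "(") {
      if (left$kind != "id")
        expr_syntax_error("call requires a function name", tk$pos)
      args <- list()
      if (expr_peek(st)$text != ")" || expr_peek(st)$type != "op") {
        repeat {
          args[[length(args) + 1L]] <- expr_parse_bp(st, 0L)
          nx <- expr_peek(st)
          if (nx$type == "op" && nx$text == ",") { expr_next(st); next }
          break
        }
      }
      expr_expect(st, ")")
      left <- list(kind = "call", name = left$name, args = args)
    } else if (tk$text == "[") {
      idx <- expr_parse_bp(st, 0L)
      expr_expect(st, "]")
      left <- list(kind = "index", obj = left, index = idx)
    } else if (tk$text == "**") {
      # right-associative: recurse at bp - 1
      rhs <- expr_parse_bp(st, bp - 1L)
      left <- list(kind = "binop", op = "**", lhs = left, rhs = rhs)
    } else {
      rhs <- expr_parse_bp(st, bp)
      left <- list(kind = "binop", op = tk$text, lhs = left, rhs = rhs)
    }
  }
  left
}

#' Canonical source text of a parsed expression
#'
#' Renders an AST back to a source string. Reparsing the result yields a
#' structurally identical AST.
#'
#' @param expr An `mdf_expression` or a string to parse first.
#' @return A single character string.
#' @export
expression_source <- function(expr) {
  expr <- parse_expression(expr)
  expr_render(expr$ast)
}

expr_render <- function(ast) {
  switch(ast$kind,
    num = {
      v <- ast$value
      if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
        sprintf("%.0f", v)
      } else format(v, digits = 17)
    },
    id = ast$name,
    unary = paste0("-", expr_wrap(ast$arg)),
    binop = paste0(expr_wrap(ast$lhs), " ", ast$op, " ", expr_wrap(ast$rhs)),
    call = paste0(ast$name, "(",
                  paste(vapply(ast$args, expr_render, ""), collapse = ", "),
                  ")"),
    index = paste0(expr_wrap(ast$obj), "[", expr_render(ast$index), "]"),
    stop("unknown ast kind")
  )
}

expr_wrap <- function(ast) {
  if (ast$kind %in% c("num", "id", "call", "index")) expr_render(ast)
  else paste0("(", expr_render(ast), ")")
}

#' Free identifiers of an expression
#'
#' Identifiers referenced by an expression, in order of first appearance.
#' Names used in call position (`f` in `f(x)`) are excluded; their
#' arguments are included.
#'
#' @param expr An `mdf_expression` or source string.
#' @return Character vector (possibly empty).
#' @export
free_identifiers <- function(expr) {
  expr <- parse_expression(expr)
  out <- character(0)
  walk <- function(a) {
    switch(a$kind,
      num = NULL,
      id = if (!(a$name %in% out)) out <<- c(out, a$name),
      unary = walk(a$arg),
      binop = { walk(a$lhs); walk(a$rhs) },
      call = for (ar in a$args) walk(ar),
      index = { walk(a$obj); walk(a$index) }
    )
    invisible(NULL)
  }
  walk(expr$ast)
  out
}

#' Evaluate an expression
#'
#' Evaluates a parsed expression under a set of identifier bindings and a
#' function registry. Values are numeric scalars or dense numeric arrays.
#' Scalar-array mixes broadcast elementwise; array-array operations
#' require identical shapes. Comparisons return 0/1 in the broadcast
#' shape. Division by zero follows IEEE semantics (Inf/NaN) rather than
#' raising.
#'
#' @param expr An `mdf_expression` or source string.
#' @param bindings Named list mapping identifiers to numeric values.
#' @param registry A function registry (see [core_operator_set()]);
#'   needed only when the expression calls functions.
#' @return Numeric scalar or array.
#' @export
evaluate_expression <- function(expr, bindings = list(), registry = NULL) {
  expr <- parse_expression(expr)
  expr_eval(expr$ast, bindings, registry)
}

value_shape <- function(x) if (is.null(dim(x))) length(x) else dim(x)

expr_broadcast2 <- function(op, a, b, f) {
  sa <- value_shape(a)
  sb <- value_shape(b)
  scalar_a <- is.null(dim(a)) && length(a) == 1L
  scalar_b <- is.null(dim(b)) && length(b) == 1L
  if (!scalar_a && !scalar_b && !identical(sa, sb)) {
    stop(sprintf("shape mismatch in '%s': %s vs %s", op,
                 paste(sa, collapse = "x"), paste(sb, collapse = "x")),
         call. = FALSE)
  }
  r <- f(a, b)
  storage.mode(r) <- "double"
  if (is.null(dim(r))) {
    if (!scalar_a && !is.null(dim(a))) dim(r) <- dim(a)
    else if (!scalar_b && !is.null(dim(b))) dim(r) <- dim(b)
  }
  r
}

expr_eval <- function(ast, bindings, registry) {
  switch(ast$kind,
    num = ast$value,
    id = {
      if (is.null(bindings[[ast$name]]))
        stop(sprintf("unbound identifier '%s'", ast$name), call. = FALSE)
      bindings[[ast$name]]
    },
    unary = -expr_eval(ast$arg, bindings, registry),
    binop = {
      a <- expr_eval(ast$lhs, bindings, registry)
      b <- expr_eval(ast$rhs, bindings, registry)
      op <- ast$op
      f <- switch(op,
        "+" = `+`, "-" = `-`, "*" = `*`, "/" = `/`,
        "%" = `%%`, "**" = `^`,
        "<" = function(x, y) (x < y) + 0,
        "<=" = function(x, y) (x <= y) + 0,
        ">" = function(x, y) (x > y) + 0,
        ">=" = function(x, y) (x >= y) + 0,
        "==" = function(x, y) (x == y) + 0,
        "!=" = function(x, y) (x != y) + 0
      )
      expr_broadcast2(op, a, b, f)
    },
    call = {
      if (is.null(registry))
        stop(sprintf("unknown function '%s' (no registry supplied)", ast$name),
             call. = FALSE)
      args <- lapply(ast$args, expr_eval, bindings = bindings,
                     registry = registry)
      apply_function(registry, ast$name, args)
    },
    index = {
      x <- expr_eval(ast$obj, bindings, registry)
      i <- expr_eval(ast$index, bindings, registry)
      as.numeric(x)[as.integer(i)]
    },
    stop("unknown ast kind")
  )
}
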