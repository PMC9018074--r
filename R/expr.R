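#' @useDynLib ctboolnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Boolean expressions are binary trees of plain lists:
#   list(type = "const", value = 0L|1L)
#   list(type = "var",   name  = <node name>)
#   list(type = "not",   arg   = <expr>)
#   list(type = "and"|"or", lhs = <expr>, rhs = <expr>)
# Binary operators are kept strictly binary so that the rule-robustness
# scan can address individual AND/OR occurrences.

bx_const <- function(v) list(type = "const", value = as.integer(v))
bx_var   <- function(name) list(type = "var", name = name)
bx_not   <- function(e) list(type = "not", arg = e)
bx_and   <- function(a, b) list(type = "and", lhs = a, rhs = b)
bx_or    <- function(a, b) list(type = "or", lhs = a, rhs = b)

#' Tokenise a Boolean rule string
#'
#' Accepts both the BoolNet operator spelling (`&`, `|`, `!`) and the
#' MaBoSS spelling (`AND`, `OR`, `NOT`, case-insensitive), parentheses,
#' and the constants `0`, `1`, `TRUE`, `FALSE`. Node identifiers start
#' with a letter and may contain letters, digits, `_`, `.`, `/` and `-`.
#'
#' @noRd
tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      push("lparen", "(", i); i <- i + 1L
    } else if (ch == ")") {
      push("rparen", ")", i); i <- i + 1L
    } else if (ch == "&") {
      if (substr(text, i + 1L, i + 1L) == "&") i <- i + 1L
      push("and", "&", i); i <- i + 1L
    } else if (ch == "|") {
      if (substr(text, i + 1L, i + 1L) == "|") i <- i + 1L
      push("or", "|", i); i <- i + 1L
    } else if (ch == "!") {
      push("not", "!", i); i <- i + 1L
    } else if (ch %in% c("0", "1")) {
      push("const", as.integer(ch), i); i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z][A-Za-z0-9_./-]*", substr(text, i, n)))
      word <- m[[1]]
      upper <- toupper(word)
      if (upper == "AND") push("and", word, i)
      else if (upper == "OR") push("or", word, i)
      else if (upper == "NOT") push("not", word, i)
      else if (upper == "TRUE") push("const", 1L, i)
      else if (upper == "FALSE") push("const", 0L, i)
      else push("ident", word, i)
      i <- i + nchar(word)
    } else {
      stop(sprintf("unexpected character '%s' at position %d in rule '%s'",
                   ch, i, text), call. = FALSE)
    }
  }
  tokens
}

#' Parse a Boolean rule expression
#'
#' Recursive-descent parser with the usual precedence
#' (`NOT` > `AND` > `OR`), left-associative binary operators.
#'
#' @param text rule text, e.g. `"B & !C"` or `"B AND NOT C"`.
#' @return an expression tree (see internals); use [evaluate_rule()] to
#'   evaluate it and [format_bool_expr()] to print it.
#' @export
parse_bool_expr <- function(text) {
  tokens <- tokenize_expr(text)
  if (length(tokens) == 0L)
    stop(sprintf("empty rule expression in '%s'", text), call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  fail <- function(tk, what) {
    at <- if (is.null(tk)) "end of input" else
      sprintf("'%s' at position %d", tk$value, tk$pos)
    stop(sprintf("parse error in rule '%s': expected %s, found %s",
                 text, what, at), call. = FALSE)
  }
  parse_or <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      e <- bx_or(e, parse_and())
    }
    e
  }
  parse_and <- function() {
    e <- parse_unary()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      e <- bx_and(e, parse_unary())
    }
    e
  }
  parse_unary <- function() {
    tk <- peek()
    if (is.null(tk)) fail(tk, "an operand")
    if (tk$type == "not") {
      advance()
      return(bx_not(parse_unary()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.null(tk)) fail(tk, "an operand")
    if (tk$type == "ident") { advance(); return(bx_var(tk$value)) }
    if (tk$type == "const") { advance(); return(bx_const(tk$value)) }
    if (tk$type == "lparen") {
      advance()
      e <- parse_or()
      tk2 <- peek()
      if (is.null(tk2) || tk2$type != "rparen") fail(tk2, "')'")
      advance()
      return(e)
    }
    fail(tk, "an operand")
  }
  e <- parse_or()
  if (!is.null(peek())) fail(peek(), "end of expression")
  e
}

#' Evaluate a Boolean rule on a complete network state
#'
#' @param expr an expression from [parse_bool_expr()].
#' @param state a named vector of 0/1 values covering every literal in
#'   the expression.
#' @return `0L` or `1L`.
#' @export
evaluate_rule <- function(expr, state) {
  switch(expr$type,
    const = expr$value,
    var = {
      if (is.na(match(expr$name, names(state))))
        stop(sprintf("unbound literal '%s' in rule evaluation", expr$name),
             call. = FALSE)
      as.integer(state[[expr$name]])
    },
    not = 1L - evaluate_rule(expr$arg, state),
    and = evaluate_rule(expr$lhs, state) & evaluate_rule(expr$rhs, state),
    or  = evaluate_rule(expr$lhs, state) | evaluate_rule(expr$rhs, state)
  ) |> as.integer()
}

#' Literals occurring in an expression
#' @noRd
expr_vars <- function(expr) {
  switch(expr$type,
    const = character(0),
    var = expr$name,
    not = expr_vars(expr$arg),
    unique(c(expr_vars(expr$lhs), expr_vars(expr$rhs)))
  )
}

#' Format an expression back to rule text
#'
#' @param expr expression tree.
#' @param dialect `"boolnet"` uses `& | !`; `"maboss"` uses
#'   `AND OR NOT`.
#' @return a character scalar; re-parsing it yields an identical tree.
#' @export
format_bool_expr <- function(expr, dialect = c("boolnet", "maboss")) {
  dialect <- match.arg(dialect)
  ops <- if (dialect == "boolnet") c(and = "&", or = "|", not = "!")
         else c(and = "AND", or = "OR", not = "NOT")
  # precedence: or=1, and=2, not=3, atom=4
  prec <- function(e) switch(e$type, or = 1L, and = 2L, not = 3L, 4L)
  fmt <- function(e, parent_prec) {
    out <- switch(e$type,
      const = as.character(e$value),
      var = e$name,
      not = paste0(ops[["not"]],
                   if (dialect == "maboss") " " else "",
                   fmt(e$arg, 3L)),
      and = paste(fmt(e$lhs, 2L), ops[["and"]], fmt(e$rhs, 3L)),
      or  = paste(fmt(e$lhs, 1L), ops[["or"]], fmt(e$rhs, 2L)))
    if (prec(e) < parent_prec) paste0("(", out, ")") else out
  }
  fmt(expr, 0L)
}

# Bytecode for the C++ stack machine: integer vector with opcodes
# 0 = push 0, 1 = push 1, 2 = push node value (next int: 0-based node
# index), 3 = NOT, 4 = AND, 5 = OR.  Postorder emission.
compile_expr <- function(expr, node_index) {
  switch(expr$type,
    const = as.integer(expr$value),
    var = {
      idx <- node_index[[expr$name]]
      if (is.null(idx) || is.na(idx))
        stop(sprintf("rule references undeclared node '%s'", expr$name),
             call. = FALSE)
      c(2L, idx - 1L)
    },
    not = c(compile_expr(expr$arg, node_index), 3L),
    and = c(compile_expr(expr$lhs, node_index),
            compile_expr(expr$rhs, node_index), 4L),
    or  = c(compile_expr(expr$lhs, node_index),
            compile_expr(expr$rhs, node_index), 5L)
  )
}

# Binary-operator (AND/OR) occurrences in preorder; used by the
# rule-robustness scan to address individual gates.
count_binops <- function(expr) {
  switch(expr$type,
    const = 0L, var = 0L,
    not = count_binops(expr$arg),
    1L + count_binops(expr$lhs) + count_binops(expr$rhs))
}

# Swap the i-th (preorder) AND/OR gate for its dual; i in 1..count_binops.
swap_binop <- function(expr, i) {
  stopifnot(i >= 1L, i <= count_binops(expr))
  k <- 0L
  rec <- function(e) {
    if (e$type %in% c("and", "or")) {
      k <<- k + 1L
      if (k == i) e$type <- if (e$type == "and") "or" else "and"
      e$lhs <- rec(e$lhs)
      e$rhs <- rec(e$rhs)
    } else if (e$type == "not") {
      e$arg <- rec(e$arg)
    }
    e
  }
  rec(expr)
}
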