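#' @keywords internal
"_PACKAGE"

# Rule expressions are abstract syntax trees built from plain lists:
#   list(type = "var",   name = <chr>)
#   list(type = "const", value = <lgl>)
#   list(type = "not",   arg = <expr>)
#   list(type = "and"|"or", lhs = <expr>, rhs = <expr>)
# Operator precedence follows the BoolNet convention: ! > & > |.

bp_tokenize <- function(text) {
  pat <- "[A-Za-z_][A-Za-z0-9_]*|[01]|[!&|()]|[ \t]+"
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    covered <- paste(toks, collapse = "")
    stop("invalid character in expression: '", text, "'", call. = FALSE)
  }
  toks[!grepl("^[ \t]+$", toks)]
}

bp_parse_expr <- function(text) {
  toks <- bp_tokenize(text)
  if (length(toks) == 0L) stop("empty expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of expression: '", text, "'", call. = FALSE)
    if (t == "!") {
      list(type = "not", arg = parse_factor())
    } else if (t == "(") {
      x <- parse_or()
      if (!identical(take(), ")")) {
        stop("missing ')' in expression: '", text, "'", call. = FALSE)
      }
      x
    } else if (t %in% c("0", "1")) {
      list(type = "const", value = t == "1")
    } else if (grepl("^[A-Za-z_]", t)) {
      list(type = "var", name = t)
    } else {
      stop("unexpected token '", t, "' in expression: '", text, "'", call. = FALSE)
    }
  }
  parse_and <- function() {
    x <- parse_factor()
    while (identical(peek(), "&")) {
      take()
      x <- list(type = "and", lhs = x, rhs = parse_factor())
    }
    x
  }
  parse_or <- function() {
    x <- parse_and()
    while (identical(peek(), "|")) {
      take()
      x <- list(type = "or", lhs = x, rhs = parse_and())
    }
    x
  }
  x <- parse_or()
  if (pos <= length(toks)) {
    stop("trailing tokens after expression: '", text, "'", call. = FALSE)
  }
  x
}

expr_vars <- function(expr) {
  switch(expr$type,
    var = expr$name,
    const = character(0),
    not = expr_vars(expr$arg),
    and = ,
    or = unique(c(expr_vars(expr$lhs), expr_vars(expr$rhs)))
  )
}

# Compile an AST to an R call so evaluation can be vectorized over
# logical columns (used heavily by exhaustive fixed-point enumeration).
expr_to_lang <- function(expr) {
  switch(expr$type,
    var = as.name(expr$name),
    const = expr$value,
    not = call("!", expr_to_lang(expr$arg)),
    and = call("&", expr_to_lang(expr$lhs), expr_to_lang(expr$rhs)),
    or = call("|", expr_to_lang(expr$lhs), expr_to_lang(expr$rhs))
  )
}

bp_prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)

expr_to_string <- function(expr) {
  render <- function(e, min_prec) {
    p <- bp_prec[[e$type]]
    s <- switch(e$type,
      var = e$name,
      const = if (e$value) "1" else "0",
      not = paste0("!", render(e$arg, bp_prec[["not"]])),
      and = paste0(render(e$lhs, p), " & ", render(e$rhs, p)),
      or = paste0(render(e$lhs, p), " | ", render(e$rhs, p))
    )
    if (p < min_prec) paste0("(", s, ")") else s
  }
  render(expr, 1L)
}

expr_not <- function(expr) list(type = "not", arg = expr)

#' Evaluate a rule expression under a complete assignment
#'
#' Standard Boolean semantics over an assignment of node states. The
#' expression may be given as a parsed rule (an element of
#' \code{model$rules}) or as a character string in bnet syntax.
#'
#' @param expr A rule expression, or a string such as \code{"A & !B"}.
#' @param assignment Named vector of 0/1 (or logical) values covering every
#'   variable referenced by \code{expr}.
#' @return \code{0} or \code{1}.
#' @examples
#' eval_expression("A & (B | !C)", c(A = 1, B = 0, C = 0))
#' @export
eval_expression <- function(expr, assignment) {
  if (is.character(expr)) expr <- bp_parse_expr(expr)
  vars <- expr_vars(expr)
  missing <- setdiff(vars, names(assignment))
  if (length(missing)) {
    stop("assignment is missing variable(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  env <- as.list(as.logical(assignment))
  names(env) <- names(assignment)
  as.integer(eval(expr_to_lang(expr), env))
}
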