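# Boolean models: an ordered set of named nodes, each with a logical rule.
# The declaration order is preserved and defines column order everywhere.

bp_name_rx <- "^[A-Za-z_][A-Za-z0-9_]*$"

new_boolean_model <- function(nodes, rules, source_text = NULL) {
  structure(
    list(nodes = nodes, rules = rules, source_text = source_text),
    class = "boolean_model"
  )
}

validate_boolean_model <- function(model) {
  nodes <- model$nodes
  if (anyDuplicated(nodes)) {
    stop("duplicate node declaration: ",
      paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- nodes[!grepl(bp_name_rx, nodes)]
  if (length(bad)) {
    stop("invalid node name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (n in nodes) {
    undeclared <- setdiff(expr_vars(model$rules[[n]]), nodes)
    if (length(undeclared)) {
      stop("rule for '", n, "' references undeclared variable(s): ",
        paste(undeclared, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(model)
}

#' Parse a Boolean model in BoolNet (.bnet) text format
#'
#' Accepts one \code{"Target, Expression"} line per node, an optional
#' \code{"targets, factors"} header, \code{#} comment lines and blank lines.
#' Expressions use \code{!}, \code{&}, \code{|}, parentheses and the
#' constants \code{0}/\code{1}; the separator is the first comma on the line.
#'
#' @param text A bnet-formatted string (possibly multi-line).
#' @return A \code{boolean_model}: list with \code{nodes} (character, in
#'   declaration order), \code{rules} (named list of parsed expressions) and
#'   \code{source_text}.
#' @seealso [read_bnet()], [write_bnet()], [input_nodes()]
#' @examples
#' m <- parse_bnet("targets, factors\nA, A\nB, !A")
#' m$nodes
#' @export
parse_bnet <- function(text) {
  stopifnot(is.character(text))
  lines <- strsplit(paste(text, collapse = "\n"), "\r?\n")[[1]]
  nodes <- character(0)
  rules <- list()
  header_seen <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "#")) next
    if (!header_seen && grepl("^targets[ \t]*,[ \t]*factors$", line,
      ignore.case = TRUE
    )) {
      header_seen <- TRUE
      next
    }
    header_seen <- TRUE
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L) {
      stop("line ", i, ": expected 'Target, Expression' but found no comma: '",
        line, "'",
        call. = FALSE
      )
    }
    name <- trimws(substr(line, 1L, comma - 1L))
    rhs <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!grepl(bp_name_rx, name)) {
      stop("line ", i, ": invalid node name '", name, "'", call. = FALSE)
    }
    if (name %in% nodes) {
      stop("line ", i, ": duplicate declaration of node '", name, "'",
        call. = FALSE
      )
    }
    rule <- tryCatch(bp_parse_expr(rhs), error = function(e) {
      stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    nodes <- c(nodes, name)
    rules[[name]] <- rule
  }
  if (length(nodes) == 0L) stop("no node declarations found", call. = FALSE)
  model <- new_boolean_model(nodes, rules, source_text = paste(lines, collapse = "\n"))
  validate_boolean_model(model)
  model
}

#' @rdname parse_bnet
#' @param path Path to a .bnet file.
#' @export
read_bnet <- function(path) {
  parse_bnet(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Serialize a Boolean model to BoolNet (.bnet) format
#'
#' Emits the \code{"targets, factors"} header followed by one
#' \code{"Name, expression"} line per node in declaration order. The output
#' re-parses to a semantically identical model.
#'
#' @param model A \code{boolean_model}.
#' @param path Optional file path; if given the text is also written there.
#' @return The bnet text, invisibly when \code{path} is given.
#' @export
write_bnet <- function(model, path = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  lines <- c(
    "targets, factors",
    vapply(model$nodes, function(n) {
      paste0(n, ", ", expr_to_string(model$rules[[n]]))
    }, character(1))
  )
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

is_input_rule <- function(rule, node) {
  (rule$type == "var" && rule$name == node) || rule$type == "const"
}

#' Input nodes of a Boolean model
#'
#' Inputs are the terminals of path construction: nodes with no incoming
#' regulation, encoded in bnet as a self-identity rule (\code{A, A}) or a
#' constant rule (\code{A, 0} / \code{A, 1}).
#'
#' @param model A \code{boolean_model}.
#' @return Character vector of input node names, in declaration order.
#' @export
input_nodes <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  model$nodes[vapply(model$nodes, function(n) {
    is_input_rule(model$rules[[n]], n)
  }, logical(1))]
}

#' Regulators of a node
#'
#' @param model A \code{boolean_model}.
#' @param node Node name.
#' @return Character vector of the variables referenced by the node's rule,
#'   in model declaration order.
#' @export
regulators <- function(model, node) {
  stopifnot(inherits(model, "boolean_model"))
  if (!node %in% model$nodes) stop("unknown node: ", node, call. = FALSE)
  intersect(model$nodes, expr_vars(model$rules[[node]]))
}

#' @export
print.boolean_model <- function(x, ...) {
  cat("Boolean model with", length(x$nodes), "nodes",
    paste0("(", length(input_nodes(x)), " inputs)\n"))
  for (n in x$nodes) {
    cat("  ", n, ", ", expr_to_string(x$rules[[n]]), "\n", sep = "")
  }
  invisible(x)
}
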