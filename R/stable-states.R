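# Fixed points (stable states) of a Boolean model. Fixed points are
# update-scheme independent, so no update scheme is ever chosen here.

#' Enumerate the stable states (fixed points) of a Boolean model
#'
#' Returns every complete 0/1 assignment that every rule reproduces. Two
#' strategies are available and return identical sets: exhaustive
#' (vectorized truth-table sweep of all 2^N assignments, used by default for
#' models up to \code{exhaustive_cap} nodes) and a constraint search that
#' branches on undetermined nodes and propagates forced values (used above
#' the cap). States are returned in canonical order: ascending as binary
#' words in model node order (first node most significant).
#'
#' @param model A \code{boolean_model}.
#' @param method \code{"auto"} (default), \code{"exhaustive"} or
#'   \code{"search"}.
#' @param exhaustive_cap Node-count threshold for the exhaustive strategy
#'   under \code{"auto"} (default 22).
#' @return Integer matrix, one row per stable state, columns named by node
#'   in model order. Zero rows if the model has no fixed point.
#' @examples
#' m <- parse_bnet("A, B\nB, A")
#' fixed_points(m) # (0,0) and (1,1)
#' @export
fixed_points <- function(model, method = c("auto", "exhaustive", "search"),
                         exhaustive_cap = 22L) {
  stopifnot(inherits(model, "boolean_model"))
  method <- match.arg(method)
  n <- length(model$nodes)
  if (method == "auto") {
    method <- if (n <= exhaustive_cap) "exhaustive" else "search"
  }
  states <- switch(method,
    exhaustive = fp_exhaustive(model),
    search = fp_search(model)
  )
  colnames(states) <- model$nodes
  if (nrow(states) > 1L) {
    ord <- do.call(order, as.data.frame(states))
    states <- states[ord, , drop = FALSE]
  }
  rownames(states) <- NULL
  states
}

fp_exhaustive <- function(model) {
  nodes <- model$nodes
  n <- length(nodes)
  if (n > 30L) stop("exhaustive enumeration limited to 30 nodes", call. = FALSE)
  langs <- lapply(model$rules, expr_to_lang)
  total <- 2^n
  chunk <- 2^min(n, 16L)
  rows <- list()
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start + 0:(chunk - 1)
    env <- list()
    for (j in seq_len(n)) {
      # node j takes the (n - j)-th bit: node 1 is most significant
      env[[nodes[j]]] <- (idx %/% 2^(n - j)) %% 2 == 1
    }
    ok <- rep(TRUE, length(idx))
    for (j in seq_len(n)) {
      v <- eval(langs[[j]], env)
      ok <- ok & (rep_len(v, length(idx)) == env[[nodes[j]]])
    }
    if (any(ok)) {
      rows[[length(rows) + 1L]] <-
        vapply(seq_len(n), function(j) as.integer(env[[nodes[j]]][ok]),
          integer(sum(ok))
        )
    }
  }
  if (!length(rows)) return(matrix(integer(0), 0L, n))
  m <- do.call(rbind, lapply(rows, function(r) matrix(r, ncol = n)))
  m
}

fp_search <- function(model) {
  nodes <- model$nodes
  n <- length(nodes)
  rules <- model$rules
  regs <- lapply(rules, expr_vars)
  langs <- lapply(rules, expr_to_lang)
  inputs <- input_nodes(model)
  branch_order <- c(
    match(inputs, nodes),
    setdiff(seq_len(n), match(inputs, nodes))
  )
  found <- list()
  propagate <- function(vals) {
    repeat {
      changed <- FALSE
      for (j in seq_len(n)) {
        r <- regs[[j]]
        if (length(r) && anyNA(vals[r])) next
        env <- as.list(vals[r] == 1L)
        names(env) <- r
        v <- as.integer(eval(langs[[j]], env))
        if (is.na(vals[j])) {
          vals[j] <- v
          changed <- TRUE
        } else if (vals[j] != v) {
          return(NULL)
        }
      }
      if (!changed) return(vals)
    }
  }
  rec <- function(vals) {
    vals <- propagate(vals)
    if (is.null(vals)) return(invisible())
    if (!anyNA(vals)) {
      found[[length(found) + 1L]] <<- vals
      return(invisible())
    }
    j <- branch_order[which(is.na(vals[branch_order]))[1]]
    for (v in c(0L, 1L)) {
      w <- vals
      w[j] <- v
      rec(w)
    }
  }
  start <- rep(NA_integer_, n)
  names(start) <- nodes
  rec(start)
  if (!length(found)) return(matrix(integer(0), 0L, n))
  out <- do.call(rbind, found)
  dimnames(out) <- NULL
  out
}

#' Test whether an assignment is a fixed point
#'
#' @param model A \code{boolean_model}.
#' @param assignment Named 0/1 vector covering every node.
#' @return \code{TRUE} iff every rule reproduces its node's value.
#' @export
is_fixed_point <- function(model, assignment) {
  stopifnot(inherits(model, "boolean_model"))
  missing <- setdiff(model$nodes, names(assignment))
  if (length(missing)) {
    stop("assignment is missing node(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  all(vapply(model$nodes, function(n) {
    eval_expression(model$rules[[n]], assignment) == as.integer(assignment[[n]])
  }, logical(1)))
}
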