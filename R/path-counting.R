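# Recursive reverse path construction, deduplication, classification and
# signed counting. A path is an expansion tree from a target node back to
# the inputs: at each step one true driver clause is chosen and every
# literal of the clause is expanded recursively (multi-literal clauses
# branch via a Cartesian product of their sub-path sets). Trees are
# canonicalized (children ordered by node name) so structural equality,
# and hence deduplication, is well defined.

mk_leaf <- function(node, state, truncated = FALSE) {
  lit <- if (state[[node]] == 1L) node else paste0("!", node)
  list(
    node = node, lit = lit, clause = NULL, children = list(),
    key = if (truncated) paste0(lit, "^") else lit,
    nodes = node, simple = TRUE, truncated = truncated
  )
}

mk_tree <- function(node, state, clause, children) {
  lit <- if (state[[node]] == 1L) node else paste0("!", node)
  ck <- vapply(children, `[[`, character(1), "key")
  list(
    node = node, lit = lit, clause = clause, children = children,
    key = paste0(lit, "[", clause_key(clause), "](", paste(ck, collapse = ","), ")"),
    nodes = unique(c(node, unlist(lapply(children, `[[`, "nodes")))),
    simple = length(clause) <= 1L &&
      all(vapply(children, `[[`, logical(1), "simple")),
    truncated = any(vapply(children, `[[`, logical(1), "truncated"))
  )
}

dedup_trees <- function(trees) {
  if (length(trees) <= 1L) return(trees)
  keys <- vapply(trees, `[[`, character(1), "key")
  trees[!duplicated(keys)]
}

cartesian_trees <- function(node, state, clause, child_sets, counter, max_trees) {
  combos <- list(list())
  for (s in child_sets) {
    nxt <- vector("list", length(combos) * length(s))
    k <- 0L
    for (cm in combos) {
      for (tr in s) {
        k <- k + 1L
        nxt[[k]] <- c(cm, list(tr))
      }
    }
    combos <- nxt
    counter$n <- counter$n + length(combos)
    if (counter$n > max_trees) {
      stop("path materialization exceeded ", max_trees,
        " trees; raise max_trees or use count-only mode",
        call. = FALSE
      )
    }
  }
  lapply(combos, function(ch) mk_tree(node, state, clause, ch))
}

#' Enumerate the paths explaining a node's state (reference semantics)
#'
#' Naive recursive reverse construction with an explicit per-branch visited
#' set: the target is expanded by each of its drivers; a clause with k
#' literals produces the Cartesian product of its literals' sub-path sets;
#' a branch reaching an input (or constant-rule) node terminates. A branch
#' that revisits a node either rejects the whole candidate tree
#' (\code{loop_policy = "discard"}, the default) or terminates at the
#' repeated node and keeps the tree (\code{"truncate"}). Structurally
#' identical trees are deduplicated. This routine is deliberately
#' cache-free; [count_paths()] must agree with it exactly.
#'
#' @param model A \code{boolean_model}.
#' @param state A fixed point of the model.
#' @param target Node name.
#' @param loop_policy \code{"discard"} or \code{"truncate"}.
#' @param drivers Optional \code{driver_map} (defaults to simplified
#'   drivers extracted from the state).
#' @param simplify Apply unit-lateral propagation when extracting drivers.
#' @param max_trees Materialization cap (default 1e6).
#' @return List of path trees; an input target yields its single trivial
#'   tree, a loop-sustained node under \code{"discard"} yields none.
#' @export
enumerate_paths <- function(model, state, target,
                            loop_policy = c("discard", "truncate"),
                            drivers = NULL, simplify = TRUE, max_trees = 1e6) {
  stopifnot(inherits(model, "boolean_model"))
  loop_policy <- match.arg(loop_policy)
  if (!target %in% model$nodes) stop("unknown node: ", target, call. = FALSE)
  state <- state_vector(model, state)
  dm <- resolve_drivers(model, state, drivers, simplify)
  inputs <- input_nodes(model)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  expand_naive(target, character(0), dm$drivers, state, inputs, loop_policy,
    counter, max_trees,
    cache = NULL
  )
}

resolve_drivers <- function(model, state, drivers, simplify) {
  if (is.null(drivers)) {
    dm <- extract_drivers(model, state)
    if (simplify) dm <- simplify_drivers(dm)
    dm
  } else {
    stopifnot(inherits(drivers, "driver_map"))
    drivers
  }
}

# Shared expansion engine. With cache = NULL this is the naive reference
# recursion. With a cache environment, full subtree sets are memoized per
# node and reused by materialize-then-filter: a cached tree is admissible in
# the current context iff its node set is disjoint from the visited set.
# Caching is only sound under the discard policy (a truncate expansion
# depends on the branch above), so count_paths never passes a cache when
# loop_policy = "truncate".
expand_naive <- function(node, visited, drv, state, inputs, loop_policy,
                         counter, max_trees, cache = NULL) {
  if (node %in% inputs) {
    return(list(mk_leaf(node, state)))
  }
  if (!is.null(cache) && !is.null(cache[[node]])) {
    trees <- cache[[node]]
    if (!length(visited)) return(trees)
    return(Filter(function(t) !any(t$nodes %in% visited), trees))
  }
  out <- list()
  vis2 <- c(visited, node)
  for (cl in drv[[node]]) {
    lits <- clause_canon(cl)
    child_sets <- vector("list", length(lits))
    ok <- TRUE
    if (length(lits)) {
      for (i in seq_along(lits)) {
        cn <- lit_node(lits[[i]])
        if (cn %in% vis2) {
          if (loop_policy == "discard") {
            ok <- FALSE
            break
          }
          child_sets[[i]] <- list(mk_leaf(cn, state, truncated = TRUE))
        } else {
          s <- expand_naive(
            cn, vis2, drv, state, inputs, loop_policy,
            counter, max_trees, cache
          )
          if (!length(s)) {
            ok <- FALSE
            break
          }
          child_sets[[i]] <- s
        }
      }
    }
    if (!ok) next
    out <- c(out, cartesian_trees(node, state, cl, child_sets, counter, max_trees))
  }
  out <- dedup_trees(out)
  if (!is.null(cache) && !length(visited)) cache[[node]] <- out
  out
}

# Driver dependency graph acyclicity (node -> literal nodes of its clauses).
drivers_acyclic <- function(drv, inputs) {
  color <- new.env(parent = emptyenv()) # 1 = in stack, 2 = done
  acyclic <- TRUE
  visit <- function(n) {
    st <- color[[n]]
    if (!is.null(st)) {
      if (st == 1L) acyclic <<- FALSE
      return(invisible())
    }
    color[[n]] <- 1L
    if (!n %in% inputs) {
      for (cl in drv[[n]]) {
        for (cn in lit_node(cl)) {
          visit(cn)
          if (!acyclic) break
        }
        if (!acyclic) break
      }
    }
    color[[n]] <- 2L
  }
  for (n in names(drv)) {
    visit(n)
    if (!acyclic) break
  }
  acyclic
}

# Count-only dynamic program, valid when the driver graph is acyclic: every
# expansion tree is then automatically acyclic and structurally unique, so
# counts compose by sum over clauses and product over literals.
count_dp <- function(drv, inputs, targets) {
  memo <- new.env(parent = emptyenv())
  rec <- function(n) {
    got <- memo[[n]]
    if (!is.null(got)) return(got)
    if (n %in% inputs) {
      res <- c(total = 1, simple = 1)
    } else {
      total <- 0
      simple <- 0
      for (cl in drv[[n]]) {
        if (length(cl) == 0L) {
          total <- total + 1
          simple <- simple + 1
        } else {
          sub <- lapply(lit_node(cl), rec)
          total_cl <- prod(vapply(sub, `[[`, numeric(1), "total"))
          total <- total + total_cl
          if (length(cl) == 1L) simple <- simple + sub[[1]][["simple"]]
        }
      }
      res <- c(total = total, simple = simple)
    }
    memo[[n]] <- res
    res
  }
  out <- lapply(targets, rec)
  names(out) <- targets
  out
}

count_state <- function(model, state, targets, loop_policy, simplify,
                        method, max_trees, logic = NULL, dm = NULL) {
  if (is.null(dm)) {
    dm <- if (is.null(logic)) {
      resolve_drivers(model, state, NULL, simplify)
    } else {
      d <- extract_drivers(model, state, logic)
      if (simplify) simplify_drivers(d) else d
    }
  }
  inputs <- input_nodes(model)
  acyc <- drivers_acyclic(dm$drivers, inputs)
  if (method == "auto") {
    method <- if (acyc) "dp" else if (loop_policy == "discard") "memo" else "naive"
  }
  if (method == "dp" && !acyc) {
    stop("count-only mode requires an acyclic driver structure", call. = FALSE)
  }
  if (method == "memo" && loop_policy == "truncate") method <- "naive"
  counts <- simple <- numeric(length(targets))
  names(counts) <- names(simple) <- targets
  if (method == "dp") {
    res <- count_dp(dm$drivers, inputs, targets)
    for (t in targets) {
      counts[[t]] <- res[[t]][["total"]]
      simple[[t]] <- res[[t]][["simple"]]
    }
  } else {
    cache <- if (method == "memo") new.env(parent = emptyenv()) else NULL
    counter <- new.env(parent = emptyenv())
    counter$n <- 0L
    for (t in targets) {
      trees <- expand_naive(
        t, character(0), dm$drivers, state, inputs,
        loop_policy, counter, max_trees, cache
      )
      counts[[t]] <- length(trees)
      simple[[t]] <- sum(vapply(trees, `[[`, logical(1), "simple"))
    }
  }
  sign <- ifelse(state[targets] == 1L, 1, -1)
  list(
    counts = sign * counts,
    simple = simple,
    complex = counts - simple
  )
}

#' Signed path counts for target nodes in a stable state
#'
#' The magnitude of each count is the number of distinct acyclic expansion
#' trees explaining the node's state (as enumerated by [enumerate_paths()]);
#' the sign is positive for active nodes (activation paths) and negative for
#' inactive nodes (repression paths). Counting reuses sub-path sets computed
#' for upstream nodes within the state; the result is always identical to
#' the naive enumeration.
#'
#' @inheritParams enumerate_paths
#' @param targets Character vector of node names (default: all nodes).
#' @param drivers Optional precomputed \code{driver_map} for the state
#'   (e.g. a raw, unsimplified map); overrides \code{simplify}.
#' @param method \code{"auto"} (count-only dynamic program when the driver
#'   structure is acyclic, otherwise memoized enumeration), \code{"memo"},
#'   \code{"naive"} or \code{"dp"}.
#' @return Named numeric vector of signed counts, with attributes
#'   \code{"simple"} and \code{"complex"} giving the per-node classification
#'   totals (a path is simple iff every chosen clause has one literal).
#' @examples
#' m <- parse_bnet("I1, I1\nI2, I2\nA, I1\nB, I1 & !I2\nC, A | B\nD, !C")
#' s <- c(I1 = 1, I2 = 0, A = 1, B = 1, C = 1, D = 0)
#' count_paths(m, s) # C has 2 activation paths, D 2 repression paths
#' @export
count_paths <- function(model, state, targets = NULL,
                        loop_policy = c("discard", "truncate"),
                        simplify = TRUE, drivers = NULL,
                        method = c("auto", "memo", "naive", "dp"),
                        max_trees = 1e6) {
  stopifnot(inherits(model, "boolean_model"))
  loop_policy <- match.arg(loop_policy)
  method <- match.arg(method)
  state <- state_vector(model, state)
  if (is.null(targets)) targets <- model$nodes
  unknown <- setdiff(targets, model$nodes)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(drivers)) stopifnot(inherits(drivers, "driver_map"))
  res <- count_state(
    model, state, targets, loop_policy, simplify, method,
    max_trees,
    dm = drivers
  )
  structure(res$counts, simple = res$simple, complex = res$complex)
}

#' Signed path counts for every node in every stable state
#'
#' Runs [count_paths()] for all nodes across all fixed points of the model.
#'
#' @inheritParams count_paths
#' @param states Optional precomputed state matrix (rows are fixed points);
#'   defaults to [fixed_points()].
#' @return A \code{path_count_table}: list with \code{counts},
#'   \code{simple} and \code{complex} matrices (rows in canonical state
#'   order, columns in node order), the \code{states} matrix, and the
#'   \code{loop_policy} / \code{simplified} metadata.
#' @export
count_model <- function(model, loop_policy = c("discard", "truncate"),
                        simplify = TRUE, states = NULL,
                        method = c("auto", "memo", "naive", "dp"),
                        max_trees = 1e6) {
  stopifnot(inherits(model, "boolean_model"))
  loop_policy <- match.arg(loop_policy)
  method <- match.arg(method)
  if (is.null(states)) states <- fixed_points(model)
  nodes <- model$nodes
  empty <- matrix(numeric(0), 0L, length(nodes), dimnames = list(NULL, nodes))
  if (nrow(states) == 0L) {
    warning("model has no stable state; returning an empty table")
    return(structure(
      list(
        counts = empty, simple = empty, complex = empty, states = states,
        loop_policy = loop_policy, simplified = simplify
      ),
      class = "path_count_table"
    ))
  }
  logic <- model_logic(model)
  counts <- simple <- complex <- matrix(
    0,
    nrow(states), length(nodes),
    dimnames = list(NULL, nodes)
  )
  for (i in seq_len(nrow(states))) {
    st <- state_vector(model, states[i, ])
    res <- count_state(
      model, st, nodes, loop_policy, simplify, method,
      max_trees, logic
    )
    counts[i, ] <- res$counts[nodes]
    simple[i, ] <- res$simple[nodes]
    complex[i, ] <- res$complex[nodes]
  }
  structure(
    list(
      counts = counts, simple = simple, complex = complex, states = states,
      loop_policy = loop_policy, simplified = simplify
    ),
    class = "path_count_table"
  )
}

#' @export
print.path_count_table <- function(x, ...) {
  cat(
    "Path count table:", nrow(x$counts), "stable state(s) x",
    ncol(x$counts), "node(s)\n"
  )
  cat("loop policy:", x$loop_policy, "| drivers:",
    if (x$simplified) "simplified" else "raw", "\n")
  print(x$counts)
  invisible(x)
}
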