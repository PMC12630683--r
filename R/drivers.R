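# Driver extraction and unit-lateral simplification.
#
# At a fixed point, a node's drivers are the conjunctive blocks of the
# state-appropriate minimal form (cdnf for active nodes, cndnf for inactive
# nodes) that evaluate to true under the state. They are the atomic steps of
# reverse path construction; input nodes are terminal and have no drivers.

clause_true <- function(lits, state) {
  if (length(lits) == 0L) return(TRUE)
  nodes <- lit_node(lits)
  want <- ifelse(lit_negated(lits), 0L, 1L)
  all(state[nodes] == want)
}

#' Extract the drivers of every node in a stable state
#'
#' For each non-input node, scans the minimal DNF of its rule (if the node
#' is active) or of the negated rule (if inactive) and keeps every
#' conjunctive block that evaluates to true under the state. Input and
#' constant-rule nodes are terminal and get an empty driver sequence.
#'
#' @param model A \code{boolean_model}.
#' @param state Named 0/1 vector (or one row of [fixed_points()]) that is a
#'   fixed point of the model.
#' @param logic Optional precomputed per-node logic (internal reuse).
#' @return A \code{driver_map}: list with \code{state}, \code{drivers}
#'   (named list of clause lists, canonical DNF order), \code{simplified}
#'   and \code{collapsed} flags.
#' @export
extract_drivers <- function(model, state, logic = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  state <- state_vector(model, state)
  if (!is_fixed_point(model, state)) {
    stop("state is not a fixed point of the model", call. = FALSE)
  }
  if (is.null(logic)) logic <- model_logic(model)
  inputs <- input_nodes(model)
  drivers <- vector("list", length(model$nodes))
  names(drivers) <- model$nodes
  for (n in model$nodes) {
    if (n %in% inputs) {
      drivers[[n]] <- list()
      next
    }
    dnf <- if (state[[n]] == 1L) logic[[n]]$cdnf else logic[[n]]$cndnf
    keep <- Filter(function(cl) clause_true(cl, state), dnf)
    if (length(keep) == 0L) {
      stop("internal invariant violated: no true driver clause for '", n, "'",
        call. = FALSE
      )
    }
    drivers[[n]] <- keep
  }
  structure(
    list(state = state, drivers = drivers, simplified = FALSE, collapsed = FALSE),
    class = "driver_map"
  )
}

state_vector <- function(model, state) {
  if (is.matrix(state)) {
    if (nrow(state) != 1L) stop("state must be a single assignment", call. = FALSE)
    state <- state[1L, ]
  }
  missing <- setdiff(model$nodes, names(state))
  if (length(missing)) {
    stop("state is missing node(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  s <- as.integer(state[model$nodes])
  names(s) <- model$nodes
  s
}

#' Simplify a driver map by iterative unit-lateral propagation
#'
#' Repeatedly, any node whose entire driver sequence has collapsed to a
#' single one-literal clause \code{L} is substituted verbatim for its own
#' literal in every other node's clauses (the replaced literal necessarily
#' matches the node's state, so the substitution is sign-unambiguous).
#' After each substitution, duplicate literals within a clause and duplicate
#' clauses within a node are removed. Two guards ensure termination on
#' substitution cycles: a node is used as a substitution source at most once
#' per run, and a substitution that would make a node's clause refer to the
#' node itself is skipped.
#'
#' @param dm A \code{driver_map} with \code{simplified = FALSE}.
#' @return A new \code{driver_map} with \code{simplified = TRUE}. The
#'   \code{collapsed} flag records whether any deduplication merged literals
#'   or clauses (the only case in which path counts can differ from the
#'   unsimplified map on acyclic structures).
#' @export
simplify_drivers <- function(dm) {
  stopifnot(inherits(dm, "driver_map"))
  if (isTRUE(dm$simplified)) return(dm)
  drv <- dm$drivers
  used <- character(0)
  collapsed <- FALSE
  repeat {
    changed <- FALSE
    for (x in names(drv)) {
      if (x %in% used) next
      cl <- drv[[x]]
      if (length(cl) != 1L || length(cl[[1]]) != 1L) next
      L <- cl[[1]]
      Ln <- lit_node(L)
      if (Ln == x) next
      subbed <- FALSE
      for (y in names(drv)) {
        if (y == x || y == Ln) next
        ycl <- drv[[y]]
        if (!length(ycl)) next
        hit_any <- FALSE
        ycl <- lapply(ycl, function(cc) {
          hit <- lit_node(cc) == x
          if (!any(hit)) return(cc)
          hit_any <<- TRUE
          out <- c(cc[!hit], L)
          if (anyDuplicated(out)) {
            out <- unique(out)
            collapsed <<- TRUE
          }
          clause_canon(out)
        })
        if (hit_any) {
          keys <- vapply(ycl, clause_key, character(1))
          if (anyDuplicated(keys)) {
            ycl <- ycl[!duplicated(keys)]
            collapsed <- TRUE
          }
          drv[[y]] <- ycl
          subbed <- TRUE
        }
      }
      if (subbed) {
        used <- c(used, x)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(
    list(state = dm$state, drivers = drv, simplified = TRUE, collapsed = collapsed),
    class = "driver_map"
  )
}

#' @export
print.driver_map <- function(x, ...) {
  cat("Driver map (", if (x$simplified) "simplified" else "raw", ")\n", sep = "")
  for (n in names(x$drivers)) {
    cl <- x$drivers[[n]]
    if (!length(cl)) {
      cat("  ", n, " [", x$state[[n]], "]: <input>\n", sep = "")
    } else {
      cat("  ", n, " [", x$state[[n]], "]: ",
        paste(vapply(cl, clause_key, character(1)), collapse = " ; "), "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}
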