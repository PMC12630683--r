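# Minimal disjunctive normal forms.
#
# A literal is a string "A" (positive) or "!A" (negative). A clause is a
# character vector of literals over distinct nodes; character(0) is the
# constant-true clause. A DNF is a list of clauses in canonical order:
# by clause size, then lexicographically by the clause's sorted literal text.
# The empty list is the constant-false DNF.

lit_node <- function(lits) sub("^!", "", lits)
lit_negated <- function(lits) startsWith(lits, "!")

clause_canon <- function(lits) {
  if (length(lits) == 0L) return(character(0))
  lits[order(lit_node(lits), method = "radix")]
}

clause_key <- function(lits) {
  if (length(lits) == 0L) "1" else paste(lits, collapse = " & ")
}

dnf_canon <- function(clauses) {
  clauses <- lapply(clauses, clause_canon)
  keys <- vapply(clauses, clause_key, character(1))
  clauses <- clauses[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  clauses[order(lengths(clauses), keys, method = "radix")]
}

dnf_key <- function(clauses) {
  if (length(clauses) == 0L) return("0")
  paste(vapply(clauses, clause_key, character(1)), collapse = " | ")
}

#' Render a DNF in bnet expression syntax
#'
#' @param dnf A list of clauses (character vectors of literals).
#' @return A single string, e.g. \code{"A & !B | C"}; \code{"0"} for the
#'   empty (contradictory) DNF and \code{"1"} for the constant-true clause.
#' @export
dnf_to_string <- function(dnf) dnf_key(dnf)

bp_popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# Quine-McCluskey prime implicant generation. Implicants are pairs
# (value, mask): mask bits are don't-cares, value bits under the mask are 0.
qm_primes <- function(minterms, nvars) {
  full <- bitwShiftL(1L, nvars) - 1L
  cur_value <- as.integer(minterms)
  cur_mask <- integer(length(minterms))
  primes_value <- integer(0)
  primes_mask <- integer(0)
  while (length(cur_value)) {
    k <- length(cur_value)
    combined <- logical(k)
    nxt <- new.env(parent = emptyenv())
    ones <- bp_popcount(cur_value)
    grp <- split(seq_len(k), ones)
    lv <- as.integer(names(grp))
    for (g in lv) {
      i_set <- grp[[as.character(g)]]
      j_set <- grp[[as.character(g + 1L)]]
      if (is.null(j_set)) next
      for (i in i_set) {
        for (j in j_set) {
          if (cur_mask[i] != cur_mask[j]) next
          d <- bitwXor(cur_value[i], cur_value[j])
          if (bp_popcount(d) != 1L) next
          v <- bitwAnd(cur_value[i], bitwNot(d))
          m <- bitwOr(cur_mask[i], d)
          combined[i] <- TRUE
          combined[j] <- TRUE
          assign(paste(v, m), c(v, m), envir = nxt)
        }
      }
    }
    primes_value <- c(primes_value, cur_value[!combined])
    primes_mask <- c(primes_mask, cur_mask[!combined])
    pairs <- as.list(nxt)
    if (length(pairs)) {
      mat <- do.call(rbind, pairs)
      cur_value <- as.integer(mat[, 1])
      cur_mask <- as.integer(mat[, 2])
    } else {
      cur_value <- integer(0)
      cur_mask <- integer(0)
    }
  }
  list(value = primes_value, mask = primes_mask)
}

implicant_clause <- function(value, mask, vars) {
  lits <- character(0)
  for (i in seq_along(vars)) {
    bit <- bitwShiftL(1L, i - 1L)
    if (bitwAnd(mask, bit) != 0L) next
    lits <- c(lits, if (bitwAnd(value, bit) != 0L) vars[i] else paste0("!", vars[i]))
  }
  clause_canon(lits)
}

# Exact minimum cover (Petrick-style branch and bound). Among all covers of
# minimum cardinality, the one whose canonical DNF string is lexicographically
# smallest is selected, making the result deterministic.
qm_min_cover <- function(primes, minterms, vars) {
  np <- length(primes$value)
  nm <- length(minterms)
  covers <- matrix(FALSE, np, nm)
  for (p in seq_len(np)) {
    keep <- bitwNot(primes$mask[p])
    covers[p, ] <- bitwAnd(as.integer(minterms), keep) ==
      bitwAnd(primes$value[p], keep)
  }
  # essential primes: sole cover of some minterm; part of every cover
  chosen <- integer(0)
  uncovered <- seq_len(nm)
  repeat {
    ess <- integer(0)
    for (m in uncovered) {
      cand <- which(covers[, m])
      cand <- setdiff(cand, chosen)
      if (length(cand) == 1L && !any(covers[chosen, m])) ess <- c(ess, cand)
    }
    ess <- setdiff(unique(ess), chosen)
    if (!length(ess)) break
    chosen <- c(chosen, ess)
    uncovered <- uncovered[!apply(covers[chosen, uncovered, drop = FALSE], 2, any)]
    if (!length(uncovered)) break
  }
  best_size <- Inf
  best_sets <- list()
  steps <- 0L
  rec <- function(sel, unc) {
    steps <<- steps + 1L
    if (steps > 200000L) return()
    if (!length(unc)) {
      sz <- length(sel)
      if (sz < best_size) {
        best_size <<- sz
        best_sets <<- list(sort(sel))
      } else if (sz == best_size && length(best_sets) < 5000L) {
        key <- paste(sort(sel), collapse = ",")
        keys <- vapply(best_sets, paste, character(1), collapse = ",")
        if (!key %in% keys) best_sets[[length(best_sets) + 1L]] <<- sort(sel)
      }
      return()
    }
    if (length(sel) + 1L > best_size) return()
    ncand <- vapply(unc, function(m) sum(covers[, m]), numeric(1))
    m <- unc[which.min(ncand)]
    for (p in which(covers[, m])) {
      rec(c(sel, p), unc[!covers[p, unc]])
    }
  }
  rec(chosen, uncovered)
  dnfs <- lapply(best_sets, function(sel) {
    dnf_canon(lapply(sel, function(p) {
      implicant_clause(primes$value[p], primes$mask[p], vars)
    }))
  })
  keys <- vapply(dnfs, dnf_key, character(1))
  dnfs[[order(keys, method = "radix")[1]]]
}

#' Minimal DNF of a Boolean expression
#'
#' Computes a minimum-cardinality irredundant prime-implicant cover of the
#' expression (Quine-McCluskey prime generation followed by exact cover
#' selection). Among minimum covers, the lexicographically smallest canonical
#' form is returned, so the result is deterministic. A contradiction yields
#' an empty DNF; a tautology yields the single constant-true clause.
#'
#' @param expr A parsed rule expression or a bnet-syntax string.
#' @param variables Ordered character vector of variables to minimize over;
#'   defaults to the variables referenced by \code{expr}.
#' @param var_cap Maximum number of variables handled by the exhaustive
#'   truth-table backend (default 16).
#' @return A DNF: list of clauses (character vectors of literals) in
#'   canonical order.
#' @examples
#' dnf_to_string(minimal_dnf("A & B | A & !B")) # collapses to "A"
#' dnf_to_string(minimal_dnf("!(A | B)")) # "!A & !B"
#' @export
minimal_dnf <- function(expr, variables = NULL, var_cap = 16L) {
  if (is.character(expr)) expr <- bp_parse_expr(expr)
  vars <- if (is.null(variables)) expr_vars(expr) else variables
  extra <- setdiff(expr_vars(expr), vars)
  if (length(extra)) {
    stop("variables must include every variable of the expression; missing: ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(vars)
  if (n > var_cap) {
    stop("rule has ", n, " variables, above the cap of ", var_cap,
      "; raise var_cap to proceed",
      call. = FALSE
    )
  }
  if (n == 0L) {
    v <- eval(expr_to_lang(expr), list())
    return(if (v) list(character(0)) else list())
  }
  ms <- 0:(2^n - 1L)
  env <- list()
  for (i in seq_len(n)) {
    env[[vars[i]]] <- bitwAnd(ms, bitwShiftL(1L, i - 1L)) != 0L
  }
  vals <- eval(expr_to_lang(expr), env)
  vals <- rep_len(vals, length(ms)) # constants evaluate to length 1
  minterms <- ms[vals]
  if (length(minterms) == 0L) return(list())
  if (length(minterms) == length(ms)) return(list(character(0)))
  primes <- qm_primes(minterms, n)
  qm_min_cover(primes, minterms, vars)
}

#' State-appropriate minimal forms of a node's rule
#'
#' Returns the minimal DNF of the rule (\code{cdnf}, explaining the active
#' state) and of its negation (\code{cndnf}, explaining the inactive state),
#' both over the rule's own variables. The two are contradictory and jointly
#' exhaustive.
#'
#' @param model A \code{boolean_model}.
#' @param node Node name.
#' @param var_cap Passed on to [minimal_dnf()].
#' @return List with elements \code{node}, \code{cdnf}, \code{cndnf}.
#' @export
node_logic <- function(model, node, var_cap = 16L) {
  stopifnot(inherits(model, "boolean_model"))
  if (!node %in% model$nodes) stop("unknown node: ", node, call. = FALSE)
  rule <- model$rules[[node]]
  vars <- intersect(model$nodes, expr_vars(rule))
  list(
    node = node,
    cdnf = minimal_dnf(rule, vars, var_cap),
    cndnf = minimal_dnf(expr_not(rule), vars, var_cap)
  )
}

# node_logic for every node, computed once per model
model_logic <- function(model, var_cap = 16L) {
  logic <- lapply(model$nodes, function(n) node_logic(model, n, var_cap))
  names(logic) <- model$nodes
  logic
}
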